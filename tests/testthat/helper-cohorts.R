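# A constructed cohort with one planted single-trait-defect variety:
# "DEF" is the best variety on five benefit traits but by far the worst on
# the lodging grade (cost), while "MED" is uniformly decent. Compensatory
# scoring (PCA) rewards DEF's overall excellence; regret-constrained scoring
# (VIKOR) must demote it.
planted_defect_cohort <- function(seed = 1, n_background = 18) {
  set.seed(seed)
  codes <- c("PH", "PSD", "FFH", "FBT", "FGH", "PLR")
  factor_ <- rnorm(n_background)
  bg_benefit <- sapply(1:5, function(j) 50 + 4 * factor_ + rnorm(n_background, 0, 2))
  bg_plr <- runif(n_background, 0, 0.3)
  m <- rbind(
    cbind(bg_benefit, bg_plr),
    DEF = c(rep(65, 5), 2.2),
    MED = c(rep(55, 5), 0.1)
  )
  dimnames(m) <- list(c(paste0("B", seq_len(n_background)), "DEF", "MED"),
                      codes)
  trait_matrix(m, registry = default_registry())
}
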