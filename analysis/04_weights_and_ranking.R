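#!/usr/bin/env Rscript
# CRITIC objective weighting and VIKOR compromise ranking per cohort, plus
# the auxiliary multivariate views, via the one-call evaluation pipeline.

library(mechadapt)

for (grp in c("erect", "pendent")) {
  x <- read_trait_matrix(file.path("results/cohorts", paste0(grp, "_traits.csv")),
                         group = grp)
  run <- run_evaluation(x, out_dir = file.path("results", paste0(grp, "_run")))
  w <- run$critic[order(-run$critic$weight), ]
  cat(sprintf("%s cohort: top-4 CRITIC weights %s\n", grp,
              paste(sprintf("%s %.2f%%", w$code[1:4], w$weight_percent[1:4]),
                    collapse = ", ")))
  best <- run$vikor[order(run$vikor$rank), ][1:3, ]
  cat(sprintf("  VIKOR top-3: %s (Qi = %s)\n",
              paste(best$variety, collapse = ", "),
              paste(sprintf("%.3f", best$q), collapse = ", ")))
  cat(sprintf("  PCA: %d components with eigenvalue > 1, %.1f%% cumulative\n",
              length(run$pca$retained), run$pca$cumulative_contribution))
}
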