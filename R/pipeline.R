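#' Run the full mechanization-suitability evaluation
#'
#' One reproducible pass over a cohort: variation summary, CRITIC weights,
#' VIKOR ranking, Pearson correlation report, hierarchical clustering, and
#' PCA with comprehensive scores. All tables are written as delimited text
#' under `out_dir` together with a JSON manifest capturing the configuration
#' and seed, so an identical configuration reproduces identical outputs.
#'
#' CRITIC weights are recomputed for every cohort — the weighting is
#' data-driven, so rankings are cohort-relative, not transferable across
#' cohorts.
#'
#' @param input A `trait_matrix`, a `cohort_spec` (the cohort is generated),
#'   or a path to a delimited trait-matrix file.
#' @param out_dir Output directory, created if needed; `NULL` skips writing.
#' @param registry An `indicator_registry`.
#' @param group Cohort label used when `input` is a file path.
#' @param v VIKOR compromise coefficient in \[0, 1\].
#' @param k_clusters Cluster count for the hierarchical cut.
#' @param linkage Clustering linkage, see [hierarchical_clusters()].
#' @param cor_on Basis for CRITIC correlations, see [critic_weights()].
#' @return (Invisibly) a list with `matrix`, `summary`, `critic`, `vikor`,
#'   `correlation`, `clusters`, `pca`, `pca_ranking` and `manifest`.
#' @export
run_evaluation <- function(input, out_dir = NULL,
                           registry = default_registry(),
                           group = c("other", "erect", "pendent"),
                           v = 0.5, k_clusters = 4L,
                           linkage = "average", cor_on = "normalized") {
  group <- match.arg(group)
  if (v < 0 || v > 1) stop("invalid config field v: must lie in [0, 1]")
  x <- if (inherits(input, "trait_matrix")) {
    input
  } else if (inherits(input, "cohort_spec")) {
    generate_trait_matrix(input)
  } else if (is.character(input) && length(input) == 1L) {
    read_trait_matrix(input, registry = registry, group = group)
  } else {
    stop("invalid config field input: need a trait_matrix, cohort_spec, or file path")
  }
  summary_tab <- summarize_traits(x, registry)
  critic <- critic_weights(x, registry, cor_on = cor_on)
  deg <- attr(critic, "degenerate_columns")
  if (length(deg)) {
    message("degenerate (zero-range) column(s) received weight 0: ",
            paste(deg, collapse = ", "))
  }
  vikor <- vikor_scores(x, critic, registry, v = v)
  corr <- correlation_report(x)
  clus <- hierarchical_clusters(x, k = k_clusters, linkage = linkage)
  pca <- pca_with_scores(x)
  pca_rank <- pca_ranking(pca)
  manifest <- list(
    package = "mechadapt",
    version = as.character(utils::packageVersion("mechadapt")),
    r_version = as.character(getRversion()),
    n_varieties = nrow(x), n_indicators = ncol(x),
    group = attr(x, "group"), v = v, k_clusters = k_clusters,
    linkage = linkage, cor_on = cor_on,
    seed = if (inherits(input, "cohort_spec")) input$seed else NULL,
    input = if (is.character(input)) input else class(input)[1L],
    degenerate_columns = deg
  )
  res <- list(matrix = x, summary = summary_tab, critic = critic,
              vikor = vikor, correlation = corr, clusters = clus,
              pca = pca, pca_ranking = pca_rank, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(out_dir, f)
    write_trait_matrix(x, fp("trait_matrix.csv"))
    write_trait_summary(summary_tab, fp("variation_summary.csv"))
    write_critic_breakdown(critic, fp("critic_weights.csv"))
    write_vikor_result(vikor, fp("vikor_ranking.csv"))
    utils::write.csv(round(corr$r, 6), fp("correlation_r.csv"))
    utils::write.csv(signif(corr$p, 6), fp("correlation_p.csv"))
    utils::write.csv(corr$flags, fp("correlation_flags.csv"))
    utils::write.table(data.frame(variety = names(clus$labels),
                                  cluster = as.integer(clus$labels)),
                       fp("clusters.csv"), sep = ",", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(data.frame(component = seq_along(pca$eigenvalues),
                                  eigenvalue = pca$eigenvalues,
                                  contribution_percent = pca$contribution,
                                  retained = seq_along(pca$eigenvalues) %in% pca$retained),
                       fp("pca_eigenvalues.csv"), sep = ",", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(pca_rank, fp("pca_ranking.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
  }
  invisible(res)
}

#' Compare VIKOR and PCA selections on a defect trait
#'
#' The two ranking models are run on the same cohort (VIKOR on CRITIC
#' weights, PCA comprehensive scores) and, for a named trait, the extreme
#' value among each model's top-k varieties is returned. For a cost trait
#' such as the lodging grade, a smaller top-k maximum means the selection
#' better excludes varieties with that defect — the regret penalty of VIKOR
#' versus the compensatory averaging of PCA.
#'
#' @param x A `trait_matrix`.
#' @param trait_code Indicator code of the defect trait (e.g., `"PLR"`).
#' @param k Size of the head-to-head selection.
#' @param registry An `indicator_registry`.
#' @param v VIKOR compromise coefficient.
#' @param which `"max"` (default) or `"min"` extreme.
#' @return List with `vikor_extreme`, `pca_extreme`, `vikor_top`, `pca_top`.
#' @export
compare_models <- function(x, trait_code, k, registry = default_registry(),
                           v = 0.5, which = "max") {
  critic <- critic_weights(x, registry)
  vik <- vikor_scores(x, critic, registry, v = v)
  pca <- pca_ranking(pca_with_scores(x))
  list(
    vikor_extreme = topk_trait_extreme(x, vik, trait_code, k, which = which),
    pca_extreme = topk_trait_extreme(x, pca, trait_code, k, which = which),
    vikor_top = vik$variety[order(vik$rank)][seq_len(k)],
    pca_top = pca$variety[order(pca$rank)][seq_len(k)]
  )
}
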