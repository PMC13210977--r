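#' Pearson correlation report with significance flags
#'
#' Pairwise Pearson correlations on the raw indicator columns, two-sided
#' p-values from the t distribution with n - 2 degrees of freedom
#' (t = r sqrt(n - 2) / sqrt(1 - r^2)), and the conventional significance
#' flags: `*` at p < 0.05, `**` at p < 0.01. Zero-variance columns have
#' undefined correlations; their pairs are reported as `NA`.
#'
#' @param x A `trait_matrix` (n >= 3).
#' @return List of class `correlation_report` with elements `r`, `p`,
#'   `flags` (p x p matrices) and `n`.
#' @export
correlation_report <- function(x) {
  stopifnot(is.matrix(x))
  n <- nrow(x)
  if (n < 3L) stop("correlation significance needs at least 3 varieties")
  sds <- apply(x, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r)[sds > 0] <- 1
  rc <- pmin(pmax(r, -1), 1)
  tt <- rc * sqrt((n - 2) / pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  flags <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  flags[!is.na(p) & p < 0.05] <- "*"
  flags[!is.na(p) & p < 0.01] <- "**"
  structure(list(r = r, p = p, flags = flags, n = n),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 2L, ...) {
  cat(sprintf("Pearson correlation report over %d varieties, %d indicators\n",
              x$n, ncol(x$r)))
  shown <- matrix(paste0(formatC(x$r, format = "f", digits = digits), x$flags),
                  nrow(x$r), dimnames = dimnames(x$r))
  print(shown, quote = FALSE, ...)
  invisible(x)
}

#' Hierarchical clustering of varieties
#'
#' Varieties are clustered on z-standardized indicator columns (the 21
#' indicators mix units over orders of magnitude) under Euclidean distance.
#' The linkage is selectable; average linkage (UPGMA) is the default. The
#' assignment comes from either a requested cluster count `k` or a tree cut
#' height; labels are relabelled contiguously from 1 in order of first
#' appearance.
#'
#' @param x A `trait_matrix`.
#' @param k Number of clusters, or `NULL` to cut by height.
#' @param cut_height Dendrogram height at which to cut, if `k` is `NULL`.
#' @param linkage One of `"average"`, `"single"`, `"complete"`, `"ward.D2"`.
#' @param standardize Z-standardize columns first (default `TRUE`; constant
#'   columns are dropped with a warning).
#' @return List of class `cluster_assignment` with elements `labels` (named
#'   integer vector), `tree` (the `hclust` object), `k`, `cut_height`.
#' @export
hierarchical_clusters <- function(x, k = NULL, cut_height = NULL,
                                  linkage = c("average", "single",
                                              "complete", "ward.D2"),
                                  standardize = TRUE) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  if (is.null(k) && is.null(cut_height)) stop("supply k or cut_height")
  if (!is.null(k) && k > nrow(x)) stop("k exceeds the number of varieties")
  if (!is.null(cut_height) && cut_height < 0) stop("cut height must be non-negative")
  z <- x
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) {
      warning("dropping constant column(s): ",
              paste(colnames(x)[sds == 0], collapse = ", "))
      z <- x[, sds > 0, drop = FALSE]
    }
    z <- scale(z)
  }
  tree <- stats::hclust(stats::dist(z, method = "euclidean"), method = linkage)
  raw <- if (!is.null(k)) stats::cutree(tree, k = k) else stats::cutree(tree, h = cut_height)
  labels <- match(raw, unique(raw))  # contiguous from 1, in appearance order
  names(labels) <- rownames(x)
  structure(list(labels = labels, tree = tree,
                 k = length(unique(labels)), cut_height = cut_height),
            class = "cluster_assignment")
}

#' Principal component analysis with comprehensive variety scores
#'
#' Correlation-matrix PCA: columns are z-standardized, the eigendecomposition
#' of their correlation matrix taken, and components with eigenvalue > 1
#' retained (Kaiser rule). Each loading vector is sign-flipped so its
#' largest-magnitude entry is positive, making scores reproducible. The
#' comprehensive score of a variety is the contribution-weighted sum over
#' retained components: sum_m (contribution_m / cumulative contribution) *
#' score_im, so the component weights sum to 1.
#'
#' @param x A `trait_matrix`; constant columns are dropped with a warning.
#' @return List of class `pca_model` with `eigenvalues`, `loadings`,
#'   `scores` (varieties x components), `contribution` (percent variance per
#'   component), `retained` (indices of eigenvalue > 1 components),
#'   `cumulative_contribution` (percent, over retained),
#'   `comprehensive_score` (named vector, larger is better).
#' @export
pca_with_scores <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 3L)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  z <- scale(x)
  p <- ncol(z)
  eig <- eigen(stats::cor(x), symmetric = TRUE)
  values <- eig$values
  vectors <- eig$vectors
  for (m in seq_len(p)) {  # sign convention: dominant loading positive
    i <- which.max(abs(vectors[, m]))
    if (vectors[i, m] < 0) vectors[, m] <- -vectors[, m]
  }
  dimnames(vectors) <- list(colnames(x), paste0("PC", seq_len(p)))
  scores <- z %*% vectors
  contribution <- 100 * values / sum(values)
  retained <- which(values > 1)
  if (length(retained) == 0L) retained <- 1L  # degenerate: keep the leading PC
  cumulative <- sum(contribution[retained])
  wts <- contribution[retained] / cumulative
  comp <- as.numeric(scores[, retained, drop = FALSE] %*% wts)
  names(comp) <- rownames(x)
  structure(list(eigenvalues = values, loadings = vectors, scores = scores,
                 contribution = contribution, retained = retained,
                 cumulative_contribution = cumulative,
                 comprehensive_score = comp),
            class = "pca_model")
}

#' Rank varieties by PCA comprehensive score
#'
#' @param model A `pca_model`.
#' @return Data frame with `variety`, `score`, `rank` (rank 1 = highest
#'   comprehensive score).
#' @export
pca_ranking <- function(model) {
  stopifnot(inherits(model, "pca_model"))
  sc <- model$comprehensive_score
  ord <- order(-sc, names(sc))
  rk <- integer(length(sc))
  rk[ord] <- seq_along(sc)
  data.frame(variety = names(sc), score = as.numeric(sc), rank = rk,
             row.names = NULL, stringsAsFactors = FALSE)
}
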