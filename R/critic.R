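#' Direction-aware Min-Max normalization
#'
#' Maps each column to \[0, 1\] so that 1 is always the machine-favourable
#' end: benefit columns by (x - min) / (max - min), cost columns by
#' (max - x) / (max - min). A zero-range column carries no information; it is
#' filled with 0 and flagged degenerate rather than raising an error.
#'
#' @param x A `trait_matrix` (or numeric matrix with code colnames).
#' @param registry An `indicator_registry` giving directions.
#' @return A numeric matrix of the same shape with attribute
#'   `degenerate_columns` (character vector of zero-range codes) and class
#'   `normalized_matrix`.
#' @export
normalize_matrix <- function(x, registry = default_registry()) {
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  dirs <- indicator_directions(colnames(x), registry)
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  rng <- hi - lo
  degenerate <- colnames(x)[rng == 0]
  out <- x
  for (j in seq_len(ncol(x))) {
    if (rng[j] == 0) {
      out[, j] <- 0
    } else if (dirs[j] == "benefit") {
      out[, j] <- (x[, j] - lo[j]) / rng[j]
    } else {
      out[, j] <- (hi[j] - x[, j]) / rng[j]
    }
  }
  structure(unclass(out), degenerate_columns = degenerate,
            class = c("normalized_matrix", "matrix", "array"))
}

#' Contrast intensity of a normalized column
#'
#' The population standard deviation (1/n under the root) of a normalized
#' indicator column — the dispersion term of the CRITIC information
#' quantity. Deliberately the population form, unlike the sample SD used in
#' the descriptive variation tables.
#'
#' @param x Numeric vector (a column of a normalized matrix).
#' @return Population SD.
#' @examples
#' contrast_intensity(c(0, 0.5, 1))  # sqrt(1/6)
#' @export
contrast_intensity <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

#' Conflict of an indicator with the rest of the set
#'
#' R_j = sum_k (1 - r_jk) over the indicators k in the set, self term
#' included (it contributes 0). Plain r_jk, not |r_jk|: a negatively
#' correlated indicator carries *more* non-redundant information and raises
#' conflict.
#'
#' @param r_row Numeric vector of correlations of indicator j with every
#'   indicator (including itself, r_jj = 1).
#' @return The conflict sum.
#' @examples
#' conflict(c(1, 0, -1))  # 3
#' @export
conflict <- function(r_row) {
  if (any(abs(r_row) > 1 + 1e-8)) stop("correlations must lie in [-1, 1]")
  sum(1 - r_row)
}

#' CRITIC objective weights
#'
#' Weights each indicator by its information quantity C_j = sigma_j * R_j,
#' the product of contrast intensity (population SD of the normalized
#' column) and conflict (one minus Pearson correlation, summed over the
#' other indicators): W_j = C_j / sum(C_j). Correlations are computed on the
#' direction-aligned normalized matrix by default (so cost-column reflection
#' cannot flip signs); `cor_on = "raw"` uses the raw columns instead.
#' Degenerate (zero-range) columns get weight 0 and are excluded from the
#' conflict sums of the others.
#'
#' @param x A `trait_matrix`.
#' @param registry An `indicator_registry`.
#' @param cor_on `"normalized"` (default) or `"raw"`: data on which the
#'   pairwise Pearson correlations are computed.
#' @return A data frame of class `critic_breakdown` with columns `code`,
#'   `sigma`, `conflict`, `info`, `weight`, `weight_percent`, plus attribute
#'   `degenerate_columns`.
#' @export
critic_weights <- function(x, registry = default_registry(),
                           cor_on = c("normalized", "raw")) {
  cor_on <- match.arg(cor_on)
  stopifnot(is.matrix(x))
  if (nrow(x) < 3L) stop("CRITIC needs at least 3 varieties for correlations")
  nm <- normalize_matrix(x, registry)
  degenerate <- attr(nm, "degenerate_columns")
  codes <- colnames(x)
  active <- setdiff(codes, degenerate)
  sigma <- apply(nm, 2L, contrast_intensity)
  conf <- info <- stats::setNames(numeric(length(codes)), codes)
  if (length(active) >= 1L) {
    basis <- if (cor_on == "normalized") nm else x
    r <- stats::cor(basis[, active, drop = FALSE])
    r[abs(1 - r) < 1e-12] <- 1  # snap near-unit correlations: exact collinearity
                                # must yield exactly zero conflict
    for (code in active) conf[code] <- conflict(r[code, ])
    info[active] <- sigma[active] * conf[active]
  }
  total <- sum(info)
  w <- if (total > 0) info / total else stats::setNames(rep(0, length(codes)), codes)
  out <- data.frame(code = codes, sigma = sigma, conflict = conf, info = info,
                    weight = as.numeric(w), weight_percent = 100 * as.numeric(w),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "degenerate_columns") <- degenerate
  class(out) <- c("critic_breakdown", "data.frame")
  out
}

#' Write a CRITIC breakdown as delimited text
#'
#' @param b A `critic_breakdown`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_critic_breakdown <- function(b, path, sep = ",") {
  utils::write.table(b, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
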