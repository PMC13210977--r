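#' Coefficient of variation from summary moments
#'
#' CV% = 100 * sd / mean, the scale-free dispersion measure used throughout
#' the variation tables (and, applied to fruit measurements, as the FMU and
#' FSU indicators themselves).
#'
#' @param mean Mean value (non-zero).
#' @param sd Standard deviation.
#' @return CV percentage (vectorized).
#' @examples
#' cv_from_moments(64.43, 10.49)  # 16.28 at 2 dp
#' @export
cv_from_moments <- function(mean, sd) {
  if (any(mean == 0)) stop("coefficient of variation undefined: mean is zero")
  100 * sd / mean
}

#' Variation and diversity summary of a trait matrix
#'
#' One row per indicator with max, min, mean, sample SD (n - 1 denominator,
#' the convention for descriptive tables; the CRITIC stage separately uses
#' the population form its own formula prescribes) and CV%. A column with
#' mean 0 gets `NA` CV rather than an error.
#'
#' @param x A `trait_matrix`.
#' @param registry An `indicator_registry` supplying stage/direction labels.
#' @return A data frame of class `trait_summary` with columns `code`,
#'   `stage`, `direction`, `max`, `min`, `mean`, `sd`, `cv_percent`.
#' @export
summarize_traits <- function(x, registry = default_registry()) {
  stopifnot(is.matrix(x), nrow(x) >= 1L)
  codes <- colnames(x)
  idx <- match(codes, registry$code)
  if (anyNA(idx)) stop("unknown indicator code(s): ",
                       paste(codes[is.na(idx)], collapse = ", "))
  means <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  out <- data.frame(
    code = codes,
    stage = registry$stage[idx],
    direction = registry$direction[idx],
    max = apply(x, 2L, max),
    min = apply(x, 2L, min),
    mean = means,
    sd = sds,
    cv_percent = ifelse(means == 0, NA_real_, 100 * sds / means),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("trait_summary", "data.frame")
  out
}

#' @export
print.trait_summary <- function(x, digits = 2L, ...) {
  shown <- x
  num <- intersect(c("max", "min", "mean", "sd", "cv_percent"), names(shown))
  shown[num] <- lapply(shown[num], round, digits = digits)
  print.data.frame(shown, ...)
  invisible(x)
}

#' Write a variation summary as delimited text
#'
#' Numeric columns are rendered at 2 decimals, mirroring the conventional
#' table layout; use the returned object of [summarize_traits()] for full
#' precision.
#'
#' @param s A `trait_summary`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_trait_summary <- function(s, path, sep = ",") {
  out <- s
  num <- c("max", "min", "mean", "sd", "cv_percent")
  out[num] <- lapply(out[num], function(v) formatC(v, format = "f", digits = 2L))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
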