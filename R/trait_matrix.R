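#' Trait matrices: varieties x indicators
#'
#' A `trait_matrix` is a numeric matrix whose rows are varieties (rownames =
#' variety IDs) and whose columns are indicator codes ordered to match the
#' registry, with a `group` attribute (`"erect"`, `"pendent"` or `"other"`).
#' Downstream weight vectors align by code, not file position, so columns are
#' always reordered to registry order at assembly.
#'
#' @param values Numeric matrix or data frame of trait values.
#' @param variety_ids Character vector of unique row labels; defaults to
#'   existing rownames.
#' @param registry An `indicator_registry` giving the canonical column order.
#' @param group Cohort label.
#' @param na_action `"error"` rejects missing cells (the default: complete
#'   data is assumed and silent imputation hides measurement problems);
#'   `"impute_mean"` replaces each missing cell by its column mean.
#' @return A `trait_matrix`.
#' @export
trait_matrix <- function(values, variety_ids = rownames(values),
                         registry = default_registry(),
                         group = c("other", "erect", "pendent"),
                         na_action = c("error", "impute_mean")) {
  group <- match.arg(group)
  na_action <- match.arg(na_action)
  values <- as.matrix(values)
  if (nrow(values) == 0L) stop("trait matrix has zero rows")
  if (!is.numeric(values)) stop("non-numeric cell(s) in trait matrix")
  if (is.null(variety_ids)) stop("missing variety IDs")
  variety_ids <- as.character(variety_ids)
  if (anyDuplicated(variety_ids)) stop("duplicate variety IDs")
  if (length(variety_ids) != nrow(values)) {
    stop("variety_ids length does not match row count")
  }
  codes <- colnames(values)
  if (is.null(codes)) stop("trait matrix columns must be named by indicator code")
  unknown <- setdiff(codes, registry$code)
  if (length(unknown)) {
    stop("unknown indicator column(s): ", paste(unknown, collapse = ", "))
  }
  # registry order, restricted to the columns present
  ord <- registry$code[registry$code %in% codes]
  values <- values[, ord, drop = FALSE]
  if (anyNA(values)) {
    if (na_action == "error") {
      bad <- colnames(values)[colSums(is.na(values)) > 0L]
      stop("missing cell(s) in column(s): ", paste(bad, collapse = ", "),
           " (use na_action = \"impute_mean\" to impute)")
    }
    for (j in seq_len(ncol(values))) {
      nas <- is.na(values[, j])
      if (any(nas)) values[nas, j] <- mean(values[, j], na.rm = TRUE)
    }
  }
  rownames(values) <- variety_ids
  structure(values, group = group, class = c("trait_matrix", "matrix", "array"))
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("Trait matrix: %d varieties x %d indicators (group: %s)\n",
              nrow(x), ncol(x), attr(x, "group")))
  print(utils::head(unclass(x), 6L), ...)
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more varieties\n")
  invisible(x)
}

#' Read a trait matrix from delimited text
#'
#' Expects a header row of indicator codes and a first column of variety IDs.
#' Comma and tab delimiters are accepted (auto-detected from the header line
#' unless `sep` is given). Columns are reordered to registry order; columns
#' required by `require_all` but absent cause an error listing the missing
#' codes.
#'
#' @param path File path.
#' @param registry An `indicator_registry`.
#' @param group Cohort label stored on the result.
#' @param sep Field separator; `NULL` auto-detects comma vs tab.
#' @param require_all If `TRUE` (default) every registry indicator must be
#'   present.
#' @param na_action Passed to [trait_matrix()].
#' @return A `trait_matrix`.
#' @export
read_trait_matrix <- function(path, registry = default_registry(),
                              group = c("other", "erect", "pendent"),
                              sep = NULL, require_all = TRUE,
                              na_action = c("error", "impute_mean")) {
  group <- match.arg(group)
  stopifnot(file.exists(path))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("trait matrix file has zero data rows: ", path)
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  if (require_all) {
    absent <- setdiff(registry$code, names(vals))
    if (length(absent)) {
      stop("trait matrix is missing indicator column(s): ",
           paste(absent, collapse = ", "))
    }
  }
  non_num <- names(vals)[!vapply(vals, is.numeric, logical(1L))]
  if (length(non_num)) {
    stop("non-numeric cell(s) in column(s): ", paste(non_num, collapse = ", "))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  trait_matrix(m, registry = registry, group = group, na_action = na_action)
}

#' Write a trait matrix as delimited text
#'
#' @param x A `trait_matrix` (or plain matrix with dimnames).
#' @param path Output path.
#' @param sep Field separator (comma default).
#' @return `path`, invisibly.
#' @export
write_trait_matrix <- function(x, path, sep = ",") {
  df <- data.frame(variety = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
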