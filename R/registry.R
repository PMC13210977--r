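#' Indicator registry for mechanized transplanting and harvesting evaluation
#'
#' The evaluation system comprises 21 indicators: 8 measured on seedlings at
#' the transplanting stage and 13 on mature plants and fruits at harvest.
#' Each indicator is either a *benefit* indicator (larger is better for
#' machine operation) or a *cost* indicator (smaller is better). The lodging
#' grade PLR is a cost indicator because a larger grade means more lodging;
#' the fruit-setting-position score FSP is kept as a benefit indicator,
#' matching its established designation in this evaluation system.
#'
#' @return A data frame of class `indicator_registry` with columns `code`,
#'   `name`, `stage` (`"transplanting"` or `"harvesting"`), `direction`
#'   (`"benefit"` or `"cost"`) and `units`.
#' @examples
#' reg <- default_registry()
#' table(reg$stage)
#' table(reg$direction)
#' @export
default_registry <- function() {
  reg <- data.frame(
    code = c("SPH", "SSD", "SHL", "SCS", "SSU", "SST", "SSH", "SSDR",
             "PH", "PSD", "PCS", "FFH", "PLR", "FBT", "FMU", "FSU",
             "FGH", "FSP", "FC", "FH", "FSF"),
    name = c("Seedling plant height", "Seedling stem diameter",
             "Seedling hypocotyl length", "Seedling canopy spread",
             "Seedling stem uprightness", "Seedling stem toughness",
             "Seedling stem hardness", "Substrate disintegration rate of seedlings",
             "Plant height", "Plant stem diameter", "Plant canopy spread",
             "First bifurcation height", "Plant lodging resistance",
             "Fruiting branch toughness", "Fruit morphological uniformity",
             "Fruit size uniformity", "Lowest fruit height from the ground",
             "Fruit setting position", "Fruit color", "Fruit hardness",
             "Fruit pedicel separation force"),
    stage = rep(c("transplanting", "harvesting"), c(8L, 13L)),
    direction = c("benefit", "benefit", "benefit", "cost", "benefit",
                  "benefit", "benefit", "cost",
                  "benefit", "benefit", "cost", "benefit", "cost", "benefit",
                  "cost", "cost", "benefit", "benefit", "benefit", "benefit",
                  "cost"),
    units = c("cm", "mm", "cm", "cm", "deg", "MPa", "N", "%",
              "cm", "cm", "cm", "cm", "score", "N", "%", "%",
              "cm", "score", "a*", "N", "N"),
    stringsAsFactors = FALSE
  )
  validate_registry(reg)
}

#' Load an indicator registry from a configuration document
#'
#' Reads a JSON or YAML document with one record per indicator (fields
#' `code`, `name`, `stage`, `direction`, `units`) and validates it. With no
#' path, the built-in default registry of 21 indicators is returned.
#'
#' @param path Path to a `.json`, `.yaml`/`.yml` config file, or `NULL`.
#' @return An `indicator_registry` data frame.
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) return(default_registry())
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  recs <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  if (is.data.frame(recs)) {
    reg <- recs
  } else {
    reg <- do.call(rbind, lapply(recs, function(r) {
      as.data.frame(r[c("code", "name", "stage", "direction", "units")],
                    stringsAsFactors = FALSE)
    }))
  }
  validate_registry(reg)
}

#' Write an indicator registry to a configuration document
#'
#' @param registry An `indicator_registry`.
#' @param path Output path; format chosen by extension (`.json` default,
#'   `.yaml`/`.yml` for YAML).
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  registry <- validate_registry(registry)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- lapply(seq_len(nrow(registry)), function(i) as.list(registry[i, ]))
    yaml::write_yaml(recs, path)
  } else {
    jsonlite::write_json(registry[, c("code", "name", "stage", "direction", "units")],
                         path, dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}

validate_registry <- function(reg) {
  required <- c("code", "name", "stage", "direction", "units")
  missing <- setdiff(required, names(reg))
  if (length(missing)) {
    stop("registry is missing fields: ", paste(missing, collapse = ", "))
  }
  reg <- as.data.frame(reg[, required], stringsAsFactors = FALSE)
  if (anyDuplicated(reg$code)) {
    dup <- unique(reg$code[duplicated(reg$code)])
    stop("duplicate indicator code(s): ", paste(dup, collapse = ", "))
  }
  bad_stage <- setdiff(unique(reg$stage), c("transplanting", "harvesting"))
  if (length(bad_stage)) {
    stop("unknown stage value(s): ", paste(bad_stage, collapse = ", "))
  }
  bad_dir <- setdiff(unique(reg$direction), c("benefit", "cost"))
  if (length(bad_dir)) {
    stop("unknown direction value(s): ", paste(bad_dir, collapse = ", "))
  }
  rownames(reg) <- NULL
  class(reg) <- c("indicator_registry", "data.frame")
  reg
}

#' Direction lookup for a set of indicator codes
#'
#' @param codes Character vector of indicator codes.
#' @param registry An `indicator_registry`.
#' @return Character vector `"benefit"`/`"cost"`, named by code.
#' @keywords internal
indicator_directions <- function(codes, registry = default_registry()) {
  idx <- match(codes, registry$code)
  if (anyNA(idx)) {
    stop("unknown indicator code(s): ", paste(codes[is.na(idx)], collapse = ", "))
  }
  stats::setNames(registry$direction[idx], codes)
}
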