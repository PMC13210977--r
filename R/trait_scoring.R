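#' Substrate disintegration rate of seedlings (SSDR)
#'
#' In the standardized drop test a plug seedling free-falls onto the ground;
#' the scattered substrate (`w1`) and the substrate remaining on the roots
#' (`w2`) are weighed. SSDR = 100 * w1 / (w1 + w2) (percent). A low SSDR
#' means a cohesive root ball that survives mechanical grasping.
#'
#' Vectorized over records; masses may not be negative and each record's
#' total `w1 + w2` must be positive.
#'
#' @param w1 Mass of scattered substrate (g).
#' @param w2 Mass of substrate remaining on roots (g).
#' @return SSDR percentage(s) in \[0, 100\].
#' @examples
#' ssdr(1, 3)   # 25
#' ssdr(0, 5)   # 0: nothing scattered
#' @export
ssdr <- function(w1, w2) {
  stopifnot(length(w1) == length(w2))
  if (any(w1 < 0) || any(w2 < 0)) stop("substrate masses must be non-negative")
  total <- w1 + w2
  if (any(total == 0)) stop("degenerate drop-test record: w1 + w2 = 0")
  100 * w1 / total
}

#' Plant lodging resistance grade (PLR)
#'
#' Grades the inclination angle alpha (degrees) between the main stem and the
#' ground: grade 0 for alpha <= 15, 1 for 15 < alpha <= 30, 2 for
#' 30 < alpha <= 45, 3 for alpha > 45. Boundary angles belong to the lower
#' grade. Higher grades mean more lodging, so PLR enters the evaluation as a
#' cost indicator.
#'
#' @param alpha Inclination angle(s) in degrees, within \[0, 90\].
#' @return Integer grade(s) in `0:3`.
#' @examples
#' plr_grade(c(10, 15, 30, 45, 50))  # 0 0 1 2 3
#' @export
plr_grade <- function(alpha) {
  if (any(alpha < 0 | alpha > 90)) stop("inclination angle must lie in [0, 90] degrees")
  g <- integer(length(alpha))
  g[alpha > 15] <- 1L
  g[alpha > 30] <- 2L
  g[alpha > 45] <- 3L
  g
}

# CV% with the sample (n - 1) standard deviation; shared by the two fruit
# uniformity indicators.
cv_percent <- function(x) {
  m <- mean(x)
  if (m == 0) stop("coefficient of variation undefined: mean is zero")
  100 * stats::sd(x) / m
}

#' Fruit morphological uniformity (FMU): CV% of the fruit shape index
#'
#' The shape index of a fruit is length / diameter; morphological uniformity
#' is the coefficient of variation (percent, sample SD) of the shape index
#' over the sampled fruits (conventionally 30 per plot). A lower CV means a
#' more uniform fruit shape, so FMU is a cost indicator.
#'
#' @param lengths Fruit lengths (cm), positive.
#' @param diameters Fruit diameters (cm), positive; same length as `lengths`.
#' @return CV percentage of the shape index.
#' @export
shape_uniformity <- function(lengths, diameters) {
  if (length(lengths) != length(diameters)) {
    stop("lengths and diameters must pair one-to-one")
  }
  if (length(lengths) < 2L) stop("at least 2 fruits are required for a CV")
  if (any(lengths <= 0) || any(diameters <= 0)) {
    stop("fruit dimensions must be positive")
  }
  cv_percent(lengths / diameters)
}

#' Fruit size uniformity (FSU): CV% of the 2D projected area
#'
#' @param areas Projected fruit areas (cm^2), positive, at least 2.
#' @return CV percentage of the areas.
#' @export
size_uniformity <- function(areas) {
  if (length(areas) < 2L) stop("at least 2 fruits are required for a CV")
  if (any(areas <= 0)) stop("fruit areas must be positive")
  cv_percent(areas)
}

#' Fruit setting position score (FSP)
#'
#' One half of the side-view canopy profile is divided into six regions:
#' inner-upper (1), outer-upper (2), inner-middle (3), outer-middle (4),
#' inner-lower (5), outer-lower (6). The region holding the largest share of
#' fruits is the fruit setting position and its index is the score. Ties go
#' to the smallest region index, deterministically.
#'
#' @param counts Six non-negative fruit counts in region order.
#' @return Integer score in `1:6`.
#' @examples
#' fruit_setting_position(c(0, 0, 10, 0, 0, 0))  # 3
#' @export
fruit_setting_position <- function(counts) {
  if (length(counts) != 6L) stop("exactly six canopy-region counts are required")
  if (any(counts < 0)) stop("fruit counts must be non-negative")
  if (all(counts == 0)) stop("no fruits in any canopy region")
  which.max(counts)  # which.max takes the first maximum: smallest index wins
}

#' Trimmed replicate aggregation
#'
#' Mechanical-property replicates (e.g., nine seedlings per treatment) are
#' aggregated by excluding one occurrence of the maximum and one of the
#' minimum, then averaging the rest. With duplicated extremes exactly one
#' instance of each is removed.
#'
#' @param values Numeric replicate measurements, length >= 3.
#' @return Mean of the values after removing one max and one min.
#' @examples
#' trimmed_aggregate(c(0, 10, 10, 10, 100))  # 10
#' @export
trimmed_aggregate <- function(values) {
  if (length(values) < 3L) stop("at least 3 replicates are required")
  rest <- values[-which.max(values)]   # drop one occurrence of the max ...
  mean(rest[-which.min(rest)])         # ... then one of the min

}
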