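#' UNEP aridity index
#'
#' Ratio of mean annual precipitation to potential evapotranspiration
#' (dimensionless). Values below 0.65 indicate dryland conditions under the
#' UNEP classification; the headwater streams this package targets span
#' roughly 0.3--1.9.
#'
#' @param pp Mean annual precipitation (mm).
#' @param pet Potential evapotranspiration (mm/year); must be positive.
#' @return `pp / pet`, vectorised.
#' @examples
#' unep_aridity(833, 741)
#' @export
unep_aridity <- function(pp, pet) {
  if (!is.numeric(pp) || !is.numeric(pet)) stop("pp and pet must be numeric")
  if (any(!is.finite(pet)) || any(pet <= 0)) stop("PET must be positive and finite")
  pp / pet
}

#' de Martonne aridity index
#'
#' Annual form `PP / (T + 10)` with `PP` in mm and `T` the mean annual
#' temperature in degrees Celsius. Lower values indicate more arid climates
#' (< 10 arid, 10-20 semi-arid, > 30 humid).
#'
#' @param pp Mean annual precipitation (mm).
#' @param tmean Mean annual temperature (deg C); must exceed -10.
#' @return The index, vectorised.
#' @examples
#' de_martonne(833, 13.8)
#' @export
de_martonne <- function(pp, tmean) {
  if (!is.numeric(pp) || !is.numeric(tmean)) stop("pp and tmean must be numeric")
  if (any(!is.finite(tmean)) || any(tmean <= -10))
    stop("tmean must exceed -10 degrees C")
  pp / (tmean + 10)
}

#' Emberger bioclimatic coefficient (Q2)
#'
#' `Q2 = 2000 * PP / (M^2 - m^2)` where `M` and `m` are the mean maximum of
#' the warmest month and the mean minimum of the coldest month, both
#' converted to Kelvin. This is the classical pluviothermic quotient used to
#' place Mediterranean climates on an aridity/continentality plane; higher
#' values are wetter.
#'
#' @param pp Mean annual precipitation (mm).
#' @param tmax_jul Mean maximum temperature of the warmest month (deg C).
#' @param tmin_jan Mean minimum temperature of the coldest month (deg C).
#' @return The coefficient, vectorised.
#' @examples
#' emberger_q2(833, 29.5, 2.6)
#' @export
emberger_q2 <- function(pp, tmax_jul, tmin_jan) {
  M <- tmax_jul + 273.15
  m <- tmin_jan + 273.15
  if (any(M <= m)) stop("tmax_jul must exceed tmin_jan")
  2000 * pp / (M^2 - m^2)
}

#' Simpson diversity (1 - D)
#'
#' One minus the probability that two individuals drawn at random belong to
#' the same taxon: `1 - sum(p_i^2)` with `p_i` the relative abundances.
#' Bounded by `1 - 1/S` for `S` taxa, attained when abundances are equal.
#'
#' @param abundances Non-negative abundance (or cover) vector with at least
#'   one positive entry; need not sum to one.
#' @return Simpson 1 - D, in `[0, 1)`.
#' @examples
#' simpson_diversity(c(0.7, 0.2, 0.1))
#' @export
simpson_diversity <- function(abundances) {
  if (!is.numeric(abundances) || any(!is.finite(abundances)) || any(abundances < 0))
    stop("abundances must be finite and non-negative")
  s <- sum(abundances)
  if (s <= 0) stop("at least one abundance must be positive")
  p <- abundances / s
  1 - sum(p^2)
}

#' Arcsine-square-root transform for proportions
#'
#' `asin(sqrt(p))`, the classical variance-stabilising transform for
#' proportion/percent-cover data; strictly increasing on `[0, 1]` with range
#' `[0, pi/2]` radians. `inv_arcsine_sqrt()` is its exact inverse.
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @param theta Transformed value(s) in `[0, pi/2]` radians.
#' @return Transformed values (radians), or proportions for the inverse.
#' @examples
#' arcsine_sqrt(0.5)
#' inv_arcsine_sqrt(pi / 4)
#' @export
arcsine_sqrt <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]")
  asin(sqrt(p))
}

#' @rdname arcsine_sqrt
#' @export
inv_arcsine_sqrt <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > pi / 2 + 1e-12))
    stop("theta must lie in [0, pi/2]")
  sin(pmin(theta, pi / 2))^2
}

#' Domin-Krajina cover-abundance scale
#'
#' Published variants of the Domin-Krajina scale differ slightly, so the
#' class-bound table is an explicit, replaceable argument. The default is a
#' ten-class table whose midpoints are returned by `domin_krajina_to_percent()`
#' and inverted (by interval membership) by `percent_to_domin_krajina()`.
#'
#' @return `domin_krajina_table()`: a data frame with columns `code`,
#'   `lower`, `upper`, `midpoint` (percent cover).
#' @examples
#' domin_krajina_to_percent(10)
#' percent_to_domin_krajina(97.5)
#' @export
domin_krajina_table <- function() {
  data.frame(
    code     = 1:10,
    lower    = c(0, 0.1, 1, 5, 10, 25, 33, 50, 75, 95),
    upper    = c(0.1, 1, 5, 10, 25, 33, 50, 75, 95, 100),
    midpoint = c(0.05, 0.55, 3, 7.5, 17.5, 29, 41.5, 62.5, 85, 97.5)
  )
}

#' @rdname domin_krajina_table
#' @param code Integer class code(s) present in `table$code`.
#' @param table Lookup table, by default [domin_krajina_table()].
#' @export
domin_krajina_to_percent <- function(code, table = domin_krajina_table()) {
  i <- match(code, table$code)
  if (any(is.na(i))) {
    stop("unknown Domin-Krajina code(s): ",
         paste(unique(code[is.na(i)]), collapse = ", "))
  }
  table$midpoint[i]
}

#' @rdname domin_krajina_table
#' @param percent Percent cover in `[0, 100]`.
#' @export
percent_to_domin_krajina <- function(percent, table = domin_krajina_table()) {
  if (any(!is.finite(percent)) || any(percent < 0) || any(percent > 100))
    stop("percent must lie in [0, 100]")
  # classes are (lower, upper]; 0 belongs to the first class
  idx <- vapply(percent, function(p) {
    j <- which(p > table$lower & p <= table$upper)
    if (length(j) == 0 && p == 0) j <- 1L
    j[1]
  }, integer(1))
  table$code[idx]
}
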