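#' @title Demographics-weighted exposure machinery
#' @description
#' Population averages over the three residential-occupancy age bins
#' (under 2, 2-16, over 16): time spent at home, breathing rate, the
#' age-dependent adjustment factor (ADAF) for cancer potency, and the annual
#' volume of air breathed in the residence. All averages are population-
#' fraction-weighted convex combinations of the group values.
#' @name exposure
NULL

.check_demo <- function(demo) {
  if (!is.data.frame(demo) || nrow(demo) == 0L) {
    stop("empty or invalid demographics table")
  }
  validate_demographics(demo)
}

#' @rdname exposure
#' @param demo demographics table (see \code{\link{load_fixture_table}}).
#' @return \code{population_time_at_home}: mean fraction of the day spent at
#'   home (about 0.70 for the packaged US table).
#' @export
population_time_at_home <- function(demo) {
  demo <- .check_demo(demo)
  sum(demo$population_fraction * demo$time_at_home)
}

#' @rdname exposure
#' @return \code{population_intake_rate}: mean breathing rate in m3/day
#'   (about 14.4 for the packaged table).
#' @export
population_intake_rate <- function(demo) {
  demo <- .check_demo(demo)
  sum(demo$population_fraction * demo$intake_m3_day)
}

#' @rdname exposure
#' @param weighting \code{"population"} (default) weights ADAF by population
#'   fraction only; \code{"intake_time"} weights by each group's share of
#'   residential air intake (fraction x intake x time at home), for users who
#'   read the population-average ADAF as an intake-weighted quantity.
#' @return \code{population_adaf}: dimensionless cancer adjustment factor
#'   (1.65 population-weighted on the packaged table; printed as 1.6 after
#'   rounding).
#' @export
population_adaf <- function(demo, weighting = c("population", "intake_time")) {
  demo <- .check_demo(demo)
  weighting <- match.arg(weighting)
  w <- switch(weighting,
    population  = demo$population_fraction,
    intake_time = demo$population_fraction * demo$intake_m3_day * demo$time_at_home)
  sum(w * demo$adaf) / sum(w)
}

#' @rdname exposure
#' @details \code{annual_residential_volume} is computed group-wise
#'   (sum of fraction x intake x time-at-home x 365), not as the product of
#'   the two population averages: the volume breathed at home is an
#'   individual-level quantity aggregated over the population, and intake
#'   rate and time at home are correlated across age groups. On the packaged
#'   table the two differ by under 0.5%. Days per year is fixed at 365.
#' @return \code{annual_residential_volume}: m3 of residential air breathed
#'   per person per year (about 3,680 for the packaged table).
#' @export
annual_residential_volume <- function(demo) {
  demo <- .check_demo(demo)
  365 * sum(demo$population_fraction * demo$intake_m3_day * demo$time_at_home)
}

#' Exposure-relevant concentration increment
#'
#' The C-R functions act on the increment of exposure concentration, not the
#' raw indoor concentration; residential exposure contributes the fraction of
#' the day spent at home, so the chronic exposure-relevant concentration is
#' occupancy x indoor concentration (0.70 x indoor for the packaged
#' demographics).
#'
#' @param c_indoor indoor concentration, ug/m3 (>= 0).
#' @param occupancy fraction of time spent at home, in [0, 1].
#' @return exposure concentration increment, ug/m3.
#' @export
exposure_concentration <- function(c_indoor, occupancy = 0.7) {
  if (any(c_indoor < 0)) stop("negative concentration")
  if (occupancy < 0 || occupancy > 1) stop("occupancy must lie in [0, 1]")
  occupancy * c_indoor
}
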