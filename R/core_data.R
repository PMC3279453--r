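#' Load a packaged input table
#'
#' The package ships machine-readable copies of its four input tables:
#' population-average indoor concentrations (\code{"concentrations"}),
#' concentration-response (C-R) parameters and DALYs-per-incidence for the
#' criteria pollutants (\code{"cr_functions"}, with the nonfatal-stroke
#' complication strata in \code{"stroke_strata"}), residential occupancy
#' demographics (\code{"demographics"}), and literature-attributed excess
#' incidences for secondhand smoke, radon and acute CO poisoning
#' (\code{"attributed_outcomes"}).
#'
#' Every table is validated on load; a hand-edited fixture that violates an
#' invariant (negative concentration, population fractions not summing to one,
#' inverted confidence bounds, ...) is rejected with an error.
#'
#' @param name one of \code{"concentrations"}, \code{"cr_functions"},
#'   \code{"stroke_strata"}, \code{"demographics"},
#'   \code{"attributed_outcomes"}.
#' @param path optional path to a CSV with the same schema, overriding the
#'   packaged copy (used to run the pipeline on user-supplied tables).
#' @return a validated \code{data.frame}.
#' @examples
#' conc <- load_fixture_table("concentrations")
#' conc$mean_ugm3[conc$pollutant == "Formaldehyde"]  # 69 ug/m3
#' @export
load_fixture_table <- function(name, path = NULL) {
  tables <- c("concentrations", "cr_functions", "stroke_strata",
              "demographics", "attributed_outcomes")
  if (!is.character(name) || length(name) != 1L || !name %in% tables) {
    stop("unknown table name: ", paste(name, collapse = ", "),
         " (expected one of: ", paste(tables, collapse = ", "), ")")
  }
  if (is.null(path)) {
    path <- system.file("extdata", paste0(name, ".csv"), package = "dalyiaq",
                        mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validator <- switch(name,
    concentrations      = validate_concentrations,
    cr_functions        = validate_cr_functions,
    stroke_strata       = validate_stroke_strata,
    demographics        = validate_demographics,
    attributed_outcomes = validate_attributed_outcomes)
  validator(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(what, ": missing columns ", paste(missing, collapse = ", "))
  }
}

#' @rdname validators
#' @name validators
#' @title Input-table validators
#' @description Check the structural invariants of each input table and return
#'   the table invisibly unchanged on success. Called by
#'   \code{\link{load_fixture_table}} and by the synthetic-data generators, so
#'   generated tables obey the same contracts as the packaged ones.
#' @param df the table to validate.
#' @return the validated \code{data.frame}.
NULL

#' @rdname validators
#' @export
validate_concentrations <- function(df) {
  .require_cols(df, c("pollutant", "mean_ugm3"), "concentrations")
  if (anyDuplicated(df$pollutant)) stop("concentrations: duplicated pollutant")
  if (any(!is.finite(df$mean_ugm3)) || any(df$mean_ugm3 < 0)) {
    stop("concentrations: mean_ugm3 must be finite and >= 0")
  }
  df
}

#' @rdname validators
#' @export
validate_demographics <- function(df) {
  .require_cols(df, c("label", "population_fraction", "adaf", "time_at_home",
                      "intake_m3_day"), "demographics")
  if (nrow(df) == 0L) stop("demographics: empty table")
  frac_ok <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  if (!frac_ok(df$population_fraction)) {
    stop("demographics: population_fraction outside [0, 1]")
  }
  if (!frac_ok(df$time_at_home)) stop("demographics: time_at_home outside [0, 1]")
  if (any(df$adaf < 1)) stop("demographics: adaf must be >= 1")
  if (any(df$intake_m3_day <= 0)) stop("demographics: intake_m3_day must be > 0")
  if (abs(sum(df$population_fraction) - 1) > 0.01) {
    stop("demographics: population fractions must sum to 1 (tolerance 0.01)")
  }
  df
}

#' @rdname validators
#' @export
validate_cr_functions <- function(df) {
  .require_cols(df, c("pollutant", "outcome", "beta", "beta_lo", "beta_hi",
                      "y0", "form", "daly", "daly_lo", "daly_hi"),
                "cr_functions")
  if (any(df$beta < 0, na.rm = TRUE)) stop("cr_functions: beta must be >= 0")
  if (any(df$y0 < 0 | df$y0 > 1, na.rm = TRUE)) {
    stop("cr_functions: y0 must lie in [0, 1]")
  }
  if (!all(df$form %in% c("exponential", "linearized"))) {
    stop("cr_functions: form must be 'exponential' or 'linearized'")
  }
  bad_ci <- !is.na(df$beta_lo) & !is.na(df$beta_hi) & df$beta_lo > df$beta_hi
  if (any(bad_ci)) stop("cr_functions: inverted beta CI")
  df
}

#' @rdname validators
#' @export
validate_stroke_strata <- function(df) {
  .require_cols(df, c("stratum", "daly", "daly_lo", "daly_hi"), "stroke_strata")
  if (nrow(df) != 3L) stop("stroke_strata: expected exactly 3 strata")
  if (any(df$daly <= 0) || any(df$daly_lo > df$daly) || any(df$daly > df$daly_hi)) {
    stop("stroke_strata: require daly_lo <= daly <= daly_hi, daly > 0")
  }
  df
}

#' @rdname validators
#' @export
validate_attributed_outcomes <- function(df) {
  .require_cols(df, c("hazard", "outcome", "incidence", "incidence_lo",
                      "incidence_hi", "rate_basis", "daly", "daly_lo",
                      "daly_hi"), "attributed_outcomes")
  if (any(df$incidence < 0, na.rm = TRUE)) {
    stop("attributed_outcomes: incidence must be >= 0")
  }
  if (!all(df$rate_basis %in% c("national_count", "per_million_rate"))) {
    stop("attributed_outcomes: rate_basis must be 'national_count' or 'per_million_rate'")
  }
  has_ci <- !is.na(df$incidence_lo) & !is.na(df$incidence_hi)
  bad <- has_ci & (df$incidence_lo > df$incidence | df$incidence > df$incidence_hi)
  if (any(bad)) stop("attributed_outcomes: incidence CI must bracket the central value")
  df
}

#' Validate an ID-factor table
#'
#' Cancer and noncancer DALY-per-mass-intake characterization factors, with
#' their lognormal uncertainty factors k (the square root of the ratio of the
#' 97.5th to the 2.5th percentile; k = 1 means no uncertainty).
#'
#' @param df table with columns \code{pollutant}, \code{cancer_daly_per_kg},
#'   \code{k_cancer}, \code{noncancer_daly_per_kg}, \code{k_noncancer}.
#' @return the validated \code{data.frame}.
#' @export
validate_id_factors <- function(df) {
  .require_cols(df, c("pollutant", "cancer_daly_per_kg", "k_cancer",
                      "noncancer_daly_per_kg", "k_noncancer"), "id_factors")
  if (any(df$cancer_daly_per_kg < 0) || any(df$noncancer_daly_per_kg < 0)) {
    stop("id_factors: factors must be >= 0")
  }
  if (any(df$k_cancer < 1) || any(df$k_noncancer < 1)) {
    stop("id_factors: k must be >= 1")
  }
  df
}

#' Default US population size
#'
#' Population constant used to convert national incidence counts to rates per
#' 100,000 persons. 3.0e8 persons reproduces the secondhand-smoke attribution
#' arithmetic (national excess incidences to 51 DALYs per 100,000 per year).
#'
#' @return number of persons.
#' @export
default_population <- function() 3.0e8

#' Literature reference totals for plausibility comparison
#'
#' Populationwide DALY-loss reference constants (per 100,000 persons per
#' year): the WHO total for all noncommunicable, nonpsychiatric US diseases
#' (7,700), the portion of the top-20 US disease burden with an indoor-air
#' connection (3,000), and the estimated burden of first- and secondhand
#' tobacco smoke in industrialized nations (1,700). Burden totals above
#' \code{who_total} are flagged as implausible in reports.
#'
#' @return named list with elements \code{who_total},
#'   \code{mckenna_iaq_linked}, \code{ezzati_tobacco}.
#' @export
reference_constants <- function() {
  list(who_total = 7700, mckenna_iaq_linked = 3000, ezzati_tobacco = 1700)
}
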