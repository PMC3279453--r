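#' Literature-attributed DALY losses (radon, SHS, acute CO)
#'
#' Applies the incidence-times-DALY-factor identity to excess disease
#' incidences attributed in the literature to a hazard. Per Monte Carlo
#' sample, each outcome's incidence is drawn from a lognormal fit to its
#' 95% CI (median = printed central; point value when no CI is given), its
#' DALYs-per-incidence factor likewise, and the products are summed over
#' outcomes. Records with \code{rate_basis == "national_count"} are divided
#' by the population and expressed per 100,000; \code{"per_million_rate"}
#' records (acute CO poisoning deaths) are rescaled from per-million to
#' per-100,000 directly.
#'
#' @param outcomes attributed-outcomes table (or a hazard-filtered subset of
#'   it); see \code{\link{load_fixture_table}}.
#' @param hazard optional hazard label to filter on (e.g.
#'   \code{"radon_smoker"}).
#' @param population persons, used for national_count records.
#' @param n Monte Carlo samples (>= 1).
#' @param seed RNG seed; NULL uses the current RNG state.
#' @param degenerate collapse all uncertainty to central values.
#' @return an \code{\link{impact_summary}} in DALY/100k/yr.
#' @examples
#' tab <- load_fixture_table("attributed_outcomes")
#' attributed_dalys(tab, hazard = "acute_CO", degenerate = TRUE, n = 1)
#' # 1.53 deaths/million x 32 DALYs/death = 4.9 DALY/100k/yr
#' @export
attributed_dalys <- function(outcomes, hazard = NULL,
                             population = default_population(),
                             n = 10000, seed = 42, degenerate = FALSE) {
  stopifnot(population > 0, n >= 1)
  if (!is.null(hazard)) {
    outcomes <- outcomes[outcomes$hazard %in% hazard, , drop = FALSE]
  }
  if (nrow(outcomes) == 0L) stop("attributed_dalys: no outcomes to evaluate")
  outcomes <- validate_attributed_outcomes(outcomes)
  if (!is.null(seed)) set.seed(seed)
  total <- numeric(n)
  for (i in seq_len(nrow(outcomes))) {
    r <- outcomes[i, ]
    inc <- if (degenerate || r$incidence == 0) rep(r$incidence, n) else {
      sample_lognormal_ci(n, r$incidence, r$incidence_lo, r$incidence_hi)
    }
    daly <- if (degenerate) rep(r$daly, n) else {
      sample_lognormal_ci(n, r$daly, r$daly_lo, r$daly_hi)
    }
    per100k <- switch(r$rate_basis,
      national_count   = inc * daly / population * 1e5,
      per_million_rate = inc * daly / 10,
      stop("attributed_dalys: unknown rate_basis: ", r$rate_basis))
    total <- total + per100k
  }
  label <- if (!is.null(hazard)) paste(hazard, collapse = "+") else
    paste(unique(outcomes$hazard), collapse = "+")
  impact_summary(label, total,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 meta = list(track = "attribution", population = population))
}

#' Default secondhand-smoke component concentration increments
#'
#' Indoor concentration increments attributable to a smoker in the home, for
#' the component-based cross-check of the SHS attribution. The PM2.5
#' increment of +16 ug/m3 is the literature value; the volatile organic
#' compound increments are a synthetic stand-in set equal to each compound's
#' baseline residential concentration (smoking roughly doubles indoor
#' concentrations of the major components), since component-resolved
#' increments are not packaged. Only VOCs present in the concentrations
#' table are included.
#'
#' @param concentrations concentrations table supplying the VOC baselines.
#' @return data.frame with columns \code{pollutant}, \code{mean_ugm3}
#'   (the increments).
#' @export
shs_default_increments <- function(concentrations = load_fixture_table("concentrations")) {
  vocs <- c("1,3-Butadiene", "Acetaldehyde", "Acrolein", "Acrylonitrile",
            "Benzene", "Ethylbenzene", "Formaldehyde", "Naphthalene",
            "Styrene", "Toluene", "Xylenes")
  sub <- concentrations[concentrations$pollutant %in% vocs, c("pollutant", "mean_ugm3")]
  rbind(data.frame(pollutant = "PM2.5", mean_ugm3 = 16), sub)
}

#' Component-based SHS scenario
#'
#' Runs the two modelling tracks on the concentration increments caused by a
#' smoker in the home: PM2.5 through the epidemiology (IND) track and the
#' VOC components through the toxicology (ID) track, aggregating the aligned
#' Monte Carlo samples. Returns both the burden per 100,000 residents of
#' smoking homes and the population-averaged burden (per-smoking-home value
#' scaled by the fraction of homes with a smoker).
#'
#' @param increments concentration-increment table (columns
#'   \code{pollutant}, \code{mean_ugm3}); must include PM2.5. Defaults to
#'   \code{\link{shs_default_increments}}.
#' @param id_factors ID-factor table covering the non-PM2.5 increments
#'   (typically synthetic).
#' @param crfs C-R table for PM2.5; packaged table by default.
#' @param demo demographics table; packaged table by default.
#' @param smoking_home_fraction fraction of homes with a smoker, default 0.11.
#' @param n,seed Monte Carlo controls.
#' @return list with \code{per_smoking_home} (an
#'   \code{\link{aggregate_impacts}}) and \code{population_average} (an
#'   \code{\link{impact_summary}}).
#' @export
shs_component_scenario <- function(increments = NULL, id_factors,
                                   crfs = load_fixture_table("cr_functions"),
                                   demo = load_fixture_table("demographics"),
                                   smoking_home_fraction = 0.11,
                                   n = 10000, seed = 42) {
  if (smoking_home_fraction < 0 || smoking_home_fraction > 1) {
    stop("smoking_home_fraction must lie in [0, 1]")
  }
  if (is.null(increments)) increments <- shs_default_increments()
  increments <- validate_concentrations(increments)
  if (!"PM2.5" %in% increments$pollutant) {
    stop("shs_component_scenario: increments must include PM2.5")
  }
  per <- list()
  per[["PM2.5"]] <- ind_impact_samples("PM2.5", increments, crfs, demo,
                                       n = n, seed = seed)
  vocs <- setdiff(increments$pollutant, "PM2.5")
  for (i in seq_along(vocs)) {
    per[[vocs[i]]] <- id_impact_samples(vocs[i], increments, id_factors, demo,
                                        n = n, seed = seed + i)
  }
  agg <- aggregate_impacts(per, seed = seed)
  pop_avg <- impact_summary("SHS_components_population_average",
                            agg$total$samples * smoking_home_fraction,
                            seed = seed,
                            meta = list(smoking_home_fraction = smoking_home_fraction))
  list(per_smoking_home = agg, population_average = pop_avg)
}
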