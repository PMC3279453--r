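#' Point DALY losses from annual mass intake (ID track)
#'
#' Direct toxicological extrapolation from indoor concentration to DALYs
#' lost per person-year of breathing:
#' \deqn{DALYs = C \times V \times (CF_{cancer} \times ADAF + CF_{noncancer}),}
#' where C is the indoor concentration, V the volume of residential air
#' breathed per year, CF the cancer/noncancer characterization factors in
#' DALYs per kg of pollutant inhaled, and ADAF the age-dependent adjustment
#' factor applied to the cancer term only. The ug-to-kg conversion (1e-9)
#' is applied here, once.
#'
#' @param c_ugm3 indoor concentration, ug/m3 (>= 0).
#' @param v_m3yr residential air volume breathed, m3/yr (> 0).
#' @param cancer_daly_per_kg,noncancer_daly_per_kg characterization factors,
#'   DALY/kg intake (>= 0).
#' @param adaf dimensionless cancer age adjustment (>= 1).
#' @return DALYs per person per year.
#' @examples
#' id_dalys_point(1, 3680, cancer_daly_per_kg = 0, noncancer_daly_per_kg = 1)
#' # 3.68e-06 DALYs/person/yr
#' @export
id_dalys_point <- function(c_ugm3, v_m3yr, cancer_daly_per_kg,
                           noncancer_daly_per_kg, adaf = 1) {
  if (any(c_ugm3 < 0) || any(v_m3yr <= 0) ||
      any(cancer_daly_per_kg < 0) || any(noncancer_daly_per_kg < 0) ||
      any(adaf < 1)) {
    stop("id_dalys_point: invalid inputs (need c >= 0, v > 0, factors >= 0, adaf >= 1)")
  }
  kg_per_ug <- 1e-9
  c_ugm3 * v_m3yr * kg_per_ug *
    (cancer_daly_per_kg * adaf + noncancer_daly_per_kg)
}

#' Lognormal uncertainty factor k from CI percentiles
#'
#' The uncertainty of a characterization factor is summarized by
#' \deqn{k = (q_{97.5} / q_{2.5})^{0.5},} so that median/k and median x k
#' recover the 95% interval of the lognormal.
#'
#' @param p975,p025 97.5th and 2.5th percentiles (0 < p025 <= p975).
#' @return k >= 1.
#' @examples
#' k_from_percentiles(58000, 5600)  # 3.22
#' @export
k_from_percentiles <- function(p975, p025) {
  if (any(p025 <= 0) || any(p975 < p025)) {
    stop("k_from_percentiles: need 0 < p025 <= p975")
  }
  sqrt(p975 / p025)
}

#' Lognormal parameters from a median and uncertainty factor k
#'
#' Returns the lognormal whose median is the central estimate and whose
#' 2.5th/97.5th percentiles are median/k and median x k, i.e.
#' \code{sdlog = log(k) / 1.96}. k = 1 gives a degenerate point mass.
#'
#' @param median central estimate (> 0).
#' @param k uncertainty factor (>= 1).
#' @return list with \code{meanlog} and \code{sdlog}.
#' @export
lognormal_from_median_k <- function(median, k) {
  if (any(median <= 0) || any(k < 1)) {
    stop("lognormal_from_median_k: need median > 0 and k >= 1")
  }
  list(meanlog = log(median), sdlog = log(k) / .z975)
}

#' Monte Carlo DALY losses for a noncriteria pollutant (ID track)
#'
#' Draws the cancer and noncancer characterization factors independently
#' from their k-parameterized lognormals, applies
#' \code{\link{id_dalys_point}} with the demographics-derived annual
#' residential breathing volume and population ADAF, and scales per-person
#' DALYs by 100,000 (intake is already population-averaged, so per-person
#' losses times 100,000 are losses per 100,000 persons).
#'
#' @param pollutant pollutant name.
#' @param concentrations concentrations table.
#' @param id_factors ID-factor table (see \code{\link{validate_id_factors}});
#'   typically synthetic, see \code{\link{generate_id_factors}}.
#' @param demo demographics table.
#' @param n number of Monte Carlo samples (>= 1).
#' @param seed RNG seed; NULL uses the current RNG state.
#' @param adaf_weighting passed to \code{\link{population_adaf}}.
#' @return an \code{\link{impact_summary}} in DALY/100k/yr.
#' @export
id_impact_samples <- function(pollutant, concentrations, id_factors, demo,
                              n = 10000, seed = 42,
                              adaf_weighting = "population") {
  stopifnot(n >= 1)
  conc <- concentrations$mean_ugm3[concentrations$pollutant == pollutant]
  if (length(conc) != 1L) stop("no concentration for pollutant: ", pollutant)
  f <- id_factors[id_factors$pollutant == pollutant, , drop = FALSE]
  if (nrow(f) != 1L) stop("no ID factor for pollutant: ", pollutant)
  v <- annual_residential_volume(demo)
  adaf <- population_adaf(demo, weighting = adaf_weighting)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(median, k) {
    if (median == 0 || k == 1) return(rep(median, n))
    p <- lognormal_from_median_k(median, k)
    stats::rlnorm(n, p$meanlog, p$sdlog)
  }
  cf_c <- draw(f$cancer_daly_per_kg, f$k_cancer)
  cf_n <- draw(f$noncancer_daly_per_kg, f$k_noncancer)
  per_person <- id_dalys_point(conc, v, cf_c, cf_n, adaf = adaf)
  impact_summary(pollutant, per_person * 1e5,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 meta = list(track = "ID", adaf = adaf, v_m3yr = v))
}
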