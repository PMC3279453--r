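#' @title Lognormal and truncated-normal sampling helpers
#' @description
#' All uncertain inputs carry a central estimate and a 95% confidence
#' interval. DALY factors and incidence counts are treated as lognormal with
#' median equal to the printed central estimate and log-scale standard
#' deviation \code{log(ci_hi / ci_lo) / (2 * 1.96)}; when the printed central
#' is inconsistent with the geometric midpoint of its CI the printed central
#' still wins as the median. C-R slope coefficients are treated as normal
#' (mean = central, sd = CI width / (2 * 1.96)) truncated at zero.
#' @name sampling-helpers
NULL

.z975 <- stats::qnorm(0.975)

#' @rdname sampling-helpers
#' @param ci_lo,ci_hi 2.5th and 97.5th percentiles (both > 0).
#' @return \code{sdlog_from_ci}: log-scale standard deviation.
#' @export
sdlog_from_ci <- function(ci_lo, ci_hi) {
  if (any(ci_lo <= 0) || any(ci_hi < ci_lo)) {
    stop("lognormal CI requires 0 < ci_lo <= ci_hi")
  }
  log(ci_hi / ci_lo) / (2 * .z975)
}

#' @rdname sampling-helpers
#' @param n number of draws.
#' @param median distribution median (> 0), taken from the printed central
#'   estimate.
#' @export
sample_lognormal_ci <- function(n, median, ci_lo, ci_hi) {
  if (median <= 0) stop("lognormal median must be > 0")
  if (is.na(ci_lo) || is.na(ci_hi)) return(rep(median, n))
  sdlog <- sdlog_from_ci(ci_lo, ci_hi)
  if (sdlog == 0) return(rep(median, n))
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

#' @rdname sampling-helpers
#' @param central normal mean before truncation.
#' @details Truncation at zero is exact (inverse-CDF on the renormalized upper
#'   tail), not a clamp, so no probability atom appears at zero.
#' @export
sample_normal_ci_trunc0 <- function(n, central, ci_lo, ci_hi) {
  if (is.na(ci_lo) || is.na(ci_hi) || ci_hi == ci_lo) return(rep(central, n))
  sd <- (ci_hi - ci_lo) / (2 * .z975)
  p0 <- stats::pnorm(0, mean = central, sd = sd)
  stats::qnorm(stats::runif(n, p0, 1), mean = central, sd = sd)
}

#' Monte Carlo impact summary
#'
#' Container for one hazard's Monte Carlo sample vector of DALYs lost per
#' 100,000 persons per year, with its empirical median and 95% interval.
#'
#' @param name pollutant or hazard label.
#' @param samples numeric vector of nonnegative DALY/100k/yr draws.
#' @param seed the seed the samples were drawn under (provenance), or NA.
#' @param meta optional named list of metadata (units assumptions, fallbacks).
#' @return object of class \code{impact_summary} with fields \code{name},
#'   \code{samples}, \code{median}, \code{ci_low}, \code{ci_high},
#'   \code{n_samples}, \code{seed}, \code{meta}.
#' @export
impact_summary <- function(name, samples, seed = NA_integer_, meta = list()) {
  if (length(samples) == 0L) stop("impact_summary: empty sample vector")
  if (any(!is.finite(samples)) || any(samples < 0)) {
    stop("impact_summary: samples must be finite and >= 0")
  }
  s <- summarize_samples(samples)
  structure(
    list(name = name, samples = as.numeric(samples),
         median = s[["median"]], ci_low = s[["ci_low"]],
         ci_high = s[["ci_high"]], n_samples = length(samples),
         seed = seed, meta = meta),
    class = "impact_summary")
}

#' @export
print.impact_summary <- function(x, ...) {
  cat(sprintf("<impact_summary> %s\n", x$name))
  cat(sprintf("  median %.3g (95%% CI: %.3g, %.3g) DALY/100k/yr  [n = %d]\n",
              x$median, x$ci_low, x$ci_high, x$n_samples))
  invisible(x)
}

#' Summarize a Monte Carlo sample vector
#'
#' Empirical 50th, 2.5th and 97.5th percentiles (type-7 linear
#' interpolation), the reporting convention used for every central estimate
#' and 95% CI in this package.
#'
#' @param samples nonempty numeric vector.
#' @return named numeric vector \code{median}, \code{ci_low}, \code{ci_high}.
#' @export
summarize_samples <- function(samples) {
  if (length(samples) == 0L) stop("summarize_samples: empty vector")
  q <- stats::quantile(samples, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
  c(median = q[1], ci_low = q[2], ci_high = q[3])
}

#' Aggregate aligned per-pollutant Monte Carlo samples
#'
#' Sums sample vectors element-wise across pollutants (the vectors must come
#' from the same Monte Carlo run, so sample i of the total is the sum of
#' sample i of every pollutant) and computes the dominance decomposition: for
#' each pollutant, the fraction of samples in which it is the single largest
#' contributor to the total. Ties are broken in favour of the first-listed
#' pollutant, a measure-zero event for continuous draws.
#'
#' @param per_pollutant named list of \code{\link{impact_summary}} objects
#'   with equal-length sample vectors.
#' @param seed seed recorded for provenance.
#' @return object of class \code{aggregate_impacts}: \code{total} (an
#'   \code{impact_summary}), \code{per_pollutant}, \code{dominance} (named
#'   fractions summing to 1 over nonzero samples).
#' @export
aggregate_impacts <- function(per_pollutant, seed = NA_integer_) {
  stopifnot(length(per_pollutant) >= 1L)
  if (is.null(names(per_pollutant)) || any(names(per_pollutant) == "")) {
    names(per_pollutant) <- vapply(per_pollutant, `[[`, "", "name")
  }
  lens <- vapply(per_pollutant, function(s) length(s$samples), 0L)
  if (length(unique(lens)) != 1L) {
    stop("aggregate_impacts: misaligned sample vector lengths")
  }
  m <- vapply(per_pollutant, `[[`, numeric(lens[1]), "samples")
  if (is.null(dim(m))) m <- matrix(m, ncol = length(per_pollutant),
                                   dimnames = list(NULL, names(per_pollutant)))
  total <- rowSums(m)
  winner <- max.col(m, ties.method = "first")
  dominance <- vapply(seq_along(per_pollutant), function(j) mean(winner == j), 0)
  names(dominance) <- colnames(m)
  structure(
    list(total = impact_summary("total", total, seed = seed),
         per_pollutant = per_pollutant,
         dominance = dominance,
         sample_matrix = m,
         seed = seed),
    class = "aggregate_impacts")
}

#' @export
print.aggregate_impacts <- function(x, ...) {
  cat(sprintf("<aggregate_impacts> %d pollutants, n = %d samples\n",
              length(x$per_pollutant), x$total$n_samples))
  cat(sprintf("  total median %.3g (95%% CI: %.3g, %.3g) DALY/100k/yr\n",
              x$total$median, x$total$ci_low, x$total$ci_high))
  dom <- sort(x$dominance, decreasing = TRUE)
  top <- utils::head(dom[dom > 0], 3)
  cat("  dominant contributor shares:",
      paste(sprintf("%s %.0f%%", names(top), 100 * top), collapse = ", "), "\n")
  invisible(x)
}

#' Super-threshold share statistic
#'
#' Fraction of Monte Carlo samples in which a named subset of pollutants
#' contributes more than \code{share_threshold} of the total DALY losses
#' (e.g. "in 90% of samples, acrolein + formaldehyde + PM2.5 contributed
#' more than 80% of the total").
#'
#' @param agg an \code{\link{aggregate_impacts}} object.
#' @param subset character vector of pollutant names.
#' @param share_threshold fraction in (0, 1].
#' @return fraction of samples in [0, 1]. Samples with zero total are counted
#'   as not exceeding the threshold.
#' @export
dominant_share <- function(agg, subset, share_threshold) {
  stopifnot(inherits(agg, "aggregate_impacts"),
            length(subset) >= 1L,
            share_threshold > 0, share_threshold <= 1)
  unknown <- setdiff(subset, colnames(agg$sample_matrix))
  if (length(unknown) > 0L) {
    stop("dominant_share: unknown pollutant(s): ", paste(unknown, collapse = ", "))
  }
  sub <- rowSums(agg$sample_matrix[, subset, drop = FALSE])
  tot <- agg$total$samples
  mean(tot > 0 & sub > share_threshold * tot)
}
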