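test_that("sample summaries are the 2.5/50/97.5 empirical percentiles", {
  expect_equal(summarize_samples(rep(3, 10)),
               c(median = 3, ci_low = 3, ci_high = 3))
  s <- summarize_samples(1:10000)
  expect_equal(s[["median"]], 5000.5)
  expect_equal(s[["ci_low"]], quantile(1:10000, 0.025, names = FALSE))
  expect_equal(summarize_samples(c(1, 3))[["median"]], 2)  # linear interpolation
  expect_error(summarize_samples(numeric(0)), "empty")
})

test_that("impact_summary enforces its invariants", {
  s <- impact_summary("x", c(1, 2, 3), seed = 5L)
  expect_s3_class(s, "impact_summary")
  expect_equal(s$median, 2)
  expect_lte(s$ci_low, s$median); expect_gte(s$ci_high, s$median)
  expect_error(impact_summary("x", numeric(0)), "empty")
  expect_error(impact_summary("x", c(1, -1)), ">= 0")
})

test_that("aggregation sums aligned samples element-wise and finds the dominant pollutant", {
  a <- impact_summary("A", rep(2, 50))
  b <- impact_summary("B", rep(3, 50))
  agg <- aggregate_impacts(list(A = a, B = b))
  expect_equal(unique(agg$total$samples), 5)
  expect_equal(agg$dominance, c(A = 0, B = 1))
  expect_equal(agg$total$samples,
               agg$per_pollutant$A$samples + agg$per_pollutant$B$samples)

  single <- aggregate_impacts(list(A = a))
  expect_equal(single$dominance, c(A = 1))
  expect_equal(dominant_share(single, "A", 0.99), 1)

  expect_error(aggregate_impacts(list(A = a, B = impact_summary("B", rep(1, 10)))),
               "misaligned")
})

test_that("super-threshold share handles exact and degenerate cases", {
  a <- impact_summary("A", rep(1, 20))
  b <- impact_summary("B", rep(1, 20))
  agg <- aggregate_impacts(list(A = a, B = b))
  expect_equal(dominant_share(agg, c("A", "B"), 0.99), 1)  # all pollutants
  expect_equal(dominant_share(agg, "A", 0.8), 0)           # exactly 50% share
  expect_error(dominant_share(agg, "C", 0.5), "unknown pollutant")
})

test_that("dominance fractions match an independent brute-force sampler", {
  # three lognormal pollutants with known parameters, checked against a
  # direct large-n resampling that never touches the package samplers
  medians <- c(A = 10, B = 6, C = 2)
  sdlogs <- c(A = 0.5, B = 0.8, C = 1.1)
  per <- lapply(names(medians), function(p) {
    set.seed(match(p, names(medians)) + 100)
    impact_summary(p, rlnorm(20000, log(medians[[p]]), sdlogs[[p]]))
  })
  names(per) <- names(medians)
  agg <- aggregate_impacts(per)

  set.seed(999)
  n_oracle <- 1e6
  m <- cbind(rlnorm(n_oracle, log(10), 0.5),
             rlnorm(n_oracle, log(6), 0.8),
             rlnorm(n_oracle, log(2), 1.1))
  oracle_dom <- tabulate(max.col(m, ties.method = "first"), 3) / n_oracle
  expect_lt(max(abs(unname(agg$dominance) - oracle_dom)), 0.02)

  oracle_share <- mean(m[, 1] + m[, 2] > 0.8 * rowSums(m))
  expect_lt(abs(dominant_share(agg, c("A", "B"), 0.8) - oracle_share), 0.02)
})

test_that("Monte Carlo error of the median shrinks roughly as n^(-1/2)", {
  med_se <- function(n, reps = 60) {
    meds <- vapply(seq_len(reps), function(r) {
      set.seed(2000 + r)
      median(rlnorm(n, log(10), 0.9))
    }, 0)
    sd(meds)
  }
  se_small <- med_se(500)
  se_large <- med_se(8000)
  ratio <- se_small / se_large   # expect about sqrt(16) = 4
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})

test_that("fixed seeds give bit-identical summaries", {
  f <- generate_id_factors(c("P1", "P2"), seed = 3)
  conc <- data.frame(pollutant = c("P1", "P2"), mean_ugm3 = c(1, 2))
  r1 <- lapply(c("P1", "P2"), id_impact_samples, conc, f, demo_tab,
               n = 1000, seed = 17)
  r2 <- lapply(c("P1", "P2"), id_impact_samples, conc, f, demo_tab,
               n = 1000, seed = 17)
  expect_identical(r1, r2)
  expect_identical(aggregate_impacts(setNames(r1, c("P1", "P2"))),
                   aggregate_impacts(setNames(r2, c("P1", "P2"))))
})
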