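test_that("point intake-DALY extrapolation applies units and ADAF correctly", {
  expect_equal(id_dalys_point(0, 3680, 5, 2, adaf = 1.65), 0)
  # 1 ug/m3 x 3680 m3/yr x 1e-9 kg/ug x 1 DALY/kg
  expect_equal(id_dalys_point(1, 3680, 0, 1), 3.68e-6)
  # ADAF scales the cancer term only
  base <- id_dalys_point(1, 1000, 1, 0, adaf = 1)
  expect_equal(id_dalys_point(1, 1000, 1, 0, adaf = 1.65), 1.65 * base)
  expect_equal(id_dalys_point(1, 1000, 0, 1, adaf = 1),
               id_dalys_point(1, 1000, 0, 1, adaf = 1.65) - 0)  # noncancer untouched
  expect_error(id_dalys_point(-1, 1000, 1, 1), "invalid")
})

test_that("point extrapolation is linear in each argument", {
  set.seed(31)
  for (i in 1:10) {
    c0 <- runif(1, 0.1, 50); v <- runif(1, 1000, 5000)
    fc <- runif(1, 0, 10); fn <- runif(1, 0, 10); a <- runif(1, 1, 3)
    x <- id_dalys_point(c0, v, fc, fn, adaf = a)
    expect_equal(id_dalys_point(2 * c0, v, fc, fn, adaf = a), 2 * x)
    expect_equal(id_dalys_point(c0, 2 * v, fc, fn, adaf = a), 2 * x)
    expect_equal(id_dalys_point(c0, v, 2 * fc, 2 * fn, adaf = a), 2 * x)
  }
})

test_that("uncertainty factor k and the k-parameterized lognormal are mutually inverse", {
  expect_equal(k_from_percentiles(58000, 5600), sqrt(58000 / 5600))
  expect_equal(round(k_from_percentiles(58000, 5600), 2), 3.22)
  expect_equal(k_from_percentiles(7, 7), 1)
  expect_equal(k_from_percentiles(100, 1), 10)
  expect_error(k_from_percentiles(1, 100), "p025 <= p975")
  expect_error(k_from_percentiles(10, -1), "0 <")

  p <- lognormal_from_median_k(10, 1)
  expect_equal(p$sdlog, 0)
  p <- lognormal_from_median_k(10, 10)
  expect_equal(qlnorm(0.025, p$meanlog, p$sdlog), 1, tolerance = 1e-9)
  expect_equal(qlnorm(0.975, p$meanlog, p$sdlog), 100, tolerance = 1e-9)
  # round-trip over a grid of medians and k
  for (k in c(1.5, 3.22, 10, 40)) {
    p <- lognormal_from_median_k(7, k)
    expect_equal(k_from_percentiles(qlnorm(0.975, p$meanlog, p$sdlog),
                                    qlnorm(0.025, p$meanlog, p$sdlog)),
                 k, tolerance = 1e-3)
  }
})

test_that("ID Monte Carlo collapses to the point value with k = 1 and is seed-stable", {
  f <- data.frame(pollutant = "X", cancer_daly_per_kg = 2, k_cancer = 1,
                  noncancer_daly_per_kg = 3, k_noncancer = 1)
  conc <- data.frame(pollutant = "X", mean_ugm3 = 5)
  res <- id_impact_samples("X", conc, f, demo_tab, n = 200, seed = 1)
  v <- annual_residential_volume(demo_tab)
  adaf <- population_adaf(demo_tab)
  expect_equal(unique(res$samples),
               1e5 * id_dalys_point(5, v, 2, 3, adaf = adaf))

  f$k_cancer <- 5; f$k_noncancer <- 8
  a <- id_impact_samples("X", conc, f, demo_tab, n = 2000, seed = 10)
  b <- id_impact_samples("X", conc, f, demo_tab, n = 2000, seed = 10)
  expect_identical(a$samples, b$samples)
})

test_that("ID sample median matches the analytic lognormal median when one factor dominates", {
  # noncancer only: impact median = c * v * 1e-9 * median_noncancer * 1e5
  f <- data.frame(pollutant = "X", cancer_daly_per_kg = 0, k_cancer = 1,
                  noncancer_daly_per_kg = 4, k_noncancer = 6)
  conc <- data.frame(pollutant = "X", mean_ugm3 = 2)
  n <- 40000
  res <- id_impact_samples("X", conc, f, demo_tab, n = n, seed = 3)
  v <- annual_residential_volume(demo_tab)
  analytic <- 1e5 * 2 * v * 1e-9 * 4
  # Monte Carlo error of the median: 1.2533 * sd / sqrt(n) on the log scale
  sdlog <- log(6) / qnorm(0.975)
  se_log <- 1.2533 * sdlog / sqrt(n)
  expect_lt(abs(log(res$median) - log(analytic)), 3 * se_log)
})

test_that("median of a two-factor sum is bracketed by sums of scaled medians", {
  f <- data.frame(pollutant = "X", cancer_daly_per_kg = 3, k_cancer = 4,
                  noncancer_daly_per_kg = 5, k_noncancer = 4)
  conc <- data.frame(pollutant = "X", mean_ugm3 = 1)
  res <- id_impact_samples("X", conc, f, demo_tab, n = 20000, seed = 5)
  v <- annual_residential_volume(demo_tab)
  adaf <- population_adaf(demo_tab)
  lo <- 1e5 * 1 * v * 1e-9 * (3 * adaf + 5) / 4
  hi <- 1e5 * 1 * v * 1e-9 * (3 * adaf + 5) * 4
  expect_gt(res$median, lo)
  expect_lt(res$median, hi)
})

test_that("ozone runs through both tracks with overlapping intervals", {
  oz_ind <- suppressMessages(
    ind_impact_samples("Ozone", conc_tab, crf_tab, demo_tab, n = 5000, seed = 8))
  f <- generate_id_factors("Ozone", magnitude_range = c(-2, 0),
                           k_range = c(5, 20), seed = 8)
  oz_id <- id_impact_samples("Ozone", conc_tab, f, demo_tab, n = 5000, seed = 8)
  expect_lt(max(oz_ind$ci_low, oz_id$ci_low),
            min(oz_ind$ci_high, oz_id$ci_high))
})
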