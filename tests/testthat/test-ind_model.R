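test_that("exponential C-R incidence matches direct evaluation and saturates", {
  # direct evaluation: -y0 (exp(-b dC) - 1) pop
  expect_equal(cr_incidence(7.4e-3, 0.0058, 11.13, 1e5),
               -7.4e-3 * (exp(-0.0058 * 11.13) - 1) * 1e5)
  expect_equal(round(cr_incidence(7.4e-3, 0.0058, 11.13, 1e5), 1), 46.3)
  expect_equal(cr_incidence(0.01, 0.5, 0, 1e5), 0)
  expect_equal(cr_incidence(0.01, 10, 1e6, 1e5), 0.01 * 1e5)  # saturation
  expect_error(cr_incidence(0.01, -1, 5, 1e5), ">= 0")
})

test_that("linearized C-R agrees with the exponential form to first order", {
  expect_equal(cr_incidence_linearized(9.5e-3, 0.004, 9.17, 1e5),
               9.5e-3 * 0.004 * 9.17 * 1e5)
  expect_equal(round(cr_incidence_linearized(9.5e-3, 0.004, 9.17, 1e5), 1), 34.8)
  expect_equal(cr_incidence_linearized(9.5e-3, 0.004, 0, 1e5), 0)
  # series expansion: relative error < 1e-6 when beta * dC = 1e-6
  lin <- cr_incidence_linearized(0.01, 1e-3, 1e-3, 1e5)
  exact <- cr_incidence(0.01, 1e-3, 1e-3, 1e5)
  expect_lt(abs(lin - exact) / exact, 1e-6)
  # missing baseline prevalence reads beta as a direct incidence rate
  expect_equal(cr_incidence_linearized(NA, 0.028, 10, 1e5),
               0.028 * 10 * 1e5)
})

test_that("C-R incidence is monotone in dose and slope, concave in dose, and linear in population", {
  set.seed(21)
  for (i in 1:20) {
    y0 <- runif(1, 1e-4, 0.05); b <- runif(1, 1e-4, 0.1)
    dc <- sort(runif(3, 0, 50))
    inc <- cr_incidence(y0, b, dc, 1e5)
    expect_true(all(diff(inc) >= 0))                       # monotone in dC
    expect_gte(cr_incidence(y0, b * 2, dc[2], 1e5), inc[2]) # monotone in beta
    # concavity: midpoint value above chord
    mid <- cr_incidence(y0, b, mean(dc[c(1, 3)]), 1e5)
    expect_gte(mid, mean(inc[c(1, 3)]) - 1e-12)
    # exponential form bounded above by its linearization
    expect_lte(inc[3], cr_incidence_linearized(y0, b, dc[3], 1e5) + 1e-12)
    # doubling population doubles incidence
    expect_equal(cr_incidence(y0, b, dc[2], 2e5), 2 * inc[2])
  }
})

test_that("stroke complication split weights the strata DALY factors", {
  expect_equal(split_stroke(3, c(9.5, 11.7, 13.1)), 3 * mean(c(9.5, 11.7, 13.1)))
  expect_equal(round(split_stroke(3, c(9.5, 11.7, 13.1)), 1), 34.3)
  expect_equal(split_stroke(2, c(9.5, 11.7, 13.1), weights = c(1, 0, 0)), 2 * 9.5)
  expect_equal(split_stroke(0, c(9.5, 11.7, 13.1)), 0)
  expect_error(split_stroke(1, c(9.5, 11.7, 13.1), weights = c(0.5, 0.4, 0.2)),
               "sum to 1")
})

test_that("degenerate-uncertainty IND sampling equals the closed-form chain", {
  demo <- demo_tab
  occ <- population_time_at_home(demo)
  res <- suppressMessages(
    ind_impact_samples("SO2", conc_tab, crf_tab, demo, n = 100, seed = 1,
                       degenerate = TRUE))
  dc <- occ * 2.9
  closed <- cr_incidence(8.0e-3, 0.002, dc, 1e5) * 4e-4
  expect_equal(unique(res$samples), closed)
  expect_equal(res$median, closed)

  # full PM2.5 chain, degenerate: mortality + bronchitis + stroke strata
  pm <- suppressMessages(
    ind_impact_samples("PM2.5", conc_tab, crf_tab, demo, n = 10, seed = 1,
                       degenerate = TRUE))
  dc <- occ * 15.9
  closed_pm <-
    cr_incidence(7.4e-3, 0.058, dc, 1e5) * 1.4 +
    cr_incidence(0.4e-3, 0.091, dc, 1e5) * 1.2 +
    split_stroke(cr_incidence(0.2e-3, 0.025, dc, 1e5), c(9.5, 11.7, 13.1))
  expect_equal(unique(pm$samples), closed_pm)
})

test_that("IND Monte Carlo is reproducible under a fixed seed", {
  a <- suppressMessages(ind_impact_samples("Ozone", conc_tab, crf_tab, demo_tab,
                                           n = 500, seed = 99))
  b <- suppressMessages(ind_impact_samples("Ozone", conc_tab, crf_tab, demo_tab,
                                           n = 500, seed = 99))
  expect_identical(a$samples, b$samples)
  one <- suppressMessages(ind_impact_samples("Ozone", conc_tab, crf_tab,
                                             demo_tab, n = 1, seed = 7))
  expect_equal(one$n_samples, 1L)
  expect_identical(one$median, one$samples)
})

test_that("IND ozone interval covers the epidemiology-track literature report", {
  oz <- suppressMessages(ind_impact_samples("Ozone", conc_tab, crf_tab,
                                            demo_tab, n = 10000, seed = 4))
  # reported central 6.7 (95% CI: 0.3, 160) under unstated slope units;
  # require overlap, not equality
  expect_lt(oz$ci_low, 6.7)
  expect_gt(oz$ci_high, 6.7)
  expect_true(all(oz$samples >= 0))
})

test_that("distribution-fitting fallbacks are logged once per flagged record", {
  msgs <- capture_messages(
    ind_impact_samples("PM2.5", conc_tab, crf_tab, demo_tab, n = 10, seed = 1))
  expect_length(grep("central_outside_ci", msgs), 1L)
  msgs2 <- capture_messages(
    ind_impact_samples("NO2", conc_tab, crf_tab, demo_tab, n = 10, seed = 1))
  expect_length(grep("y0_missing", msgs2), 1L)
})
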