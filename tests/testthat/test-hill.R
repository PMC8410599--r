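test_that("dilution series follows the constant-fold protocol", {
  s <- make_dilution_series(5e-4, 3, 7)
  expect_length(s, 7)
  expect_equal(s, 5e-4 / 3^(0:6))
  # hand-divided values of the 7-point, 3-fold, 0.5 mM protocol
  expect_equal(s[1:4], c(5e-4, 1.6667e-4, 5.5556e-5, 1.8519e-5),
               tolerance = 1e-4)
  expect_true(all(diff(s) < 0) && all(s > 0))
  expect_equal(make_dilution_series(1.0, 2, 1), 1.0)
  expect_equal(make_dilution_series(5e-4, 3, 2), c(5e-4, 1.6667e-4),
               tolerance = 1e-4)
  expect_error(make_dilution_series(-1, 3, 7), "top_concentration")
  expect_error(make_dilution_series(5e-4, 1, 7), "fold")
})

test_that("hill_response has the defining half-max, zero-dose and sign behaviour", {
  for (slope in c(0.5, 1, 2, 4)) {
    expect_equal(hill_response(1e-5, -5, 1.0, slope), 0.5)
  }
  expect_equal(hill_response(0, -5, 2, 1), 0)
  expect_equal(hill_response(1e-4, -5, 2, 1), 2 * 10 / 11, tolerance = 1e-4)
  # saturates to amplitude; sign follows amplitude
  expect_equal(hill_response(1, -6, 0.7, 1), 0.7, tolerance = 1e-5)
  expect_lt(hill_response(1e-5, -5, -0.4, 1), 0)
  expect_error(hill_response(-1e-6, -5, 1, 1), "non-negative")
})

test_that("fit_hill recovers exact parameters from noiseless data", {
  conc <- make_dilution_series(5e-4, 3, 7)
  y <- hill_response(conc, -5, 1, 1)
  f <- fit_hill(conc, y)
  expect_true(f$converged)
  expect_equal(f$log_ec50, -5, tolerance = 1e-6)
  expect_equal(f$amplitude, 1, tolerance = 1e-6)
  expect_equal(f$slope, 1, tolerance = 1e-6)
  # inhibitory ligand: negative amplitude permitted
  yneg <- hill_response(conc, -4.5, -0.6, 1.3)
  fneg <- fit_hill(conc, yneg)
  expect_equal(coef(fneg), c(log_ec50 = -4.5, amplitude = -0.6, slope = 1.3),
               tolerance = 1e-5)
})

test_that("fitted curve passes through half-max at its fitted EC50", {
  conc <- make_dilution_series(5e-4, 3, 7)
  set.seed(42)
  for (i in 1:20) {
    y <- hill_response(conc, runif(1, -6, -4), runif(1, 0.3, 1.5),
                       runif(1, 0.6, 2)) + rnorm(7, sd = 0.02)
    f <- fit_hill(conc, y)
    if (!f$converged) next
    expect_equal(predict(f, 10^f$log_ec50), f$amplitude / 2,
                 tolerance = 1e-9)
  }
})

test_that("degenerate all-zero series is flagged and ends up censored", {
  conc <- make_dilution_series(5e-4, 3, 7)
  f <- fit_hill(conc, rep(0, 7))
  expect_true(f$degenerate)
  expect_false(f$converged)
  expect_equal(f$amplitude, 0)
  cf <- apply_censoring(f)
  expect_true(cf$censored)
  expect_identical(cf$log_ec50, -2)
})

test_that("insufficient concentrations raise an error", {
  expect_error(fit_hill(c(1e-4, 1e-5, 1e-6), c(1, .5, .1)), ">= 4")
})

test_that("censoring fires on non-convergence or an EC50 above the top", {
  conc <- make_dilution_series(5e-4, 3, 7)
  good <- fit_hill(conc, hill_response(conc, -5, 1, 1))
  expect_false(apply_censoring(good, conc)$censored)
  expect_equal(apply_censoring(good, conc)$log_ec50, -5, tolerance = 1e-6)

  # EC50 of 1e-1 M is above the 5e-4 M top concentration
  high <- good
  high$log_ec50 <- -1
  ch <- apply_censoring(high, conc)
  expect_true(ch$censored)
  expect_identical(ch$log_ec50, -2)

  nonconv <- good
  nonconv$converged <- FALSE
  cn <- apply_censoring(nonconv, conc)
  expect_true(cn$censored)
  expect_identical(cn$log_ec50, -2)

  # censor value is configurable
  expect_equal(apply_censoring(nonconv, conc, censor_value = -1.5)$log_ec50,
               -1.5)
})

test_that("a non-saturating simulated series is censored at -2", {
  # true EC50 (10 mM) far above the 0.5 mM top: the series never saturates
  conc <- make_dilution_series(5e-4, 3, 7)
  y <- hill_response(conc, -2, 1, 1)
  f <- apply_censoring(fit_hill(conc, y), conc)
  expect_true(f$censored)
  expect_identical(f$log_ec50, -2)
})

test_that("activity index is the negative product of log EC50 and max dF/F", {
  expect_equal(activity_index(-5, 1.2), 6.0)
  expect_equal(activity_index(-7, 0), 0)
  expect_equal(activity_index(-2, 0.5), 1.0)  # censored case: 2 x max dF/F
  # monotonicity: higher apparent affinity or efficacy => higher index
  lecs <- seq(-8, -1, by = 0.5)
  expect_true(all(diff(sapply(lecs, activity_index, max_dff = 0.8)) < 0))
  mds <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(sapply(mds, function(m) activity_index(-5, m))) > 0))
})

test_that("noisy fits recover log EC50 with small median error", {
  conc <- make_dilution_series(5e-4, 3, 7)
  truth <- hill_response(conc, -5, 1, 1)
  set.seed(99)
  errs <- replicate(200, {
    f <- fit_hill(conc, truth + rnorm(7, sd = 0.05))
    if (f$converged) f$log_ec50 - (-5) else NA_real_
  })
  expect_gt(mean(!is.na(errs)), 0.95)
  expect_lte(median(abs(errs), na.rm = TRUE), 0.1)
})
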