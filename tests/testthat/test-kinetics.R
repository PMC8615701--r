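# Sigmoidal time-course fits, group comparisons and 4PL dose-response fits.

test_that("noise-free sigmoids are recovered to high precision", {
  t <- seq(0, 8, by = 0.5)
  v <- 0.2 + 0.7 * plogis((t - 3) / 0.4)
  fit <- fitSigmoidTime(t, v)
  expect_equal(tHalf(fit), 3, tolerance = 0.01)
  expect_equal(fit@status, "ok")
  # time-shift equivariance
  fit2 <- fitSigmoidTime(t + 2, 0.2 + 0.7 * plogis((t + 2 - 5) / 0.4))
  expect_equal(tHalf(fit2) - tHalf(fit), 2, tolerance = 1e-6)
})

test_that("degenerate series are flagged instead of fitted", {
  t <- seq(0, 8, by = 0.5)
  flat <- fitSigmoidTime(t, rep(0.5, length(t)))
  expect_false(flat@converged)
  expect_equal(flat@status, "not converged")
  expect_true(is.na(tHalf(flat)))
  expect_error(fitSigmoidTime(1:4, 1:4), "5 time points")
  expect_error(fitSigmoidTime(c(1, 1, 2, 3, 4), 1:5), "increasing")
})

test_that("a truncated rise reports the half-time as not attained", {
  # only ~20-30% of the programmed transition falls inside the window
  kin <- kineticModel(baseline = 0.2, plateau = 0.9, t50_h = 6, slope_h = 1.5)
  t <- seq(0, 4, by = 0.25)
  fit <- fitSigmoidTime(t, nuclearFractionAt(kin, t))
  expect_equal(fit@status, "not attained")
  expect_false(fit@plateau_reached)
  expect_true(is.na(tHalf(fit)))
})

test_that("programmed half-times are recovered from noisy curves", {
  kin <- kineticModel(baseline = 0.2, plateau = 0.9, t50_h = 2, slope_h = 0.4,
                      lag_h = 1)
  t <- seq(0, 8, by = 0.5)          # 17 frames
  errs <- vapply(1:100, function(s) {
    v <- simulate_ratio_curve(kin, t, noise_sd = 0.02, seed = s)
    tHalf(fitSigmoidTime(t, v)) - trueHalfTime(kin)
  }, numeric(1))
  expect_lt(median(abs(errs), na.rm = TRUE), 0.1)
})

test_that("group comparisons apply Welch tests with Bonferroni correction", {
  g <- list(a = c(1, 1.1, 0.9), b = c(2, 2.1, 1.9), c = c(1.05, 0.95, 1))
  out <- compareTHalf(g)
  expect_equal(nrow(out), 3L)
  expect_equal(out$m_tests, rep(3, 3))
  expect_equal(out$adjusted_p, pmin(1, 3 * out$raw_p))
  expect_true(all(out$adjusted_p >= out$raw_p))
  # identical groups: zero statistic, p = 1
  same <- compareTHalf(list(a = c(1, 1, 1), b = c(1, 1, 1)))
  expect_equal(same$statistic, 0)
  expect_equal(same$raw_p, 1)
  # explicit m overrides the number of pairs
  out2 <- compareTHalf(g[1:2], m_tests = 5)
  expect_equal(out2$adjusted_p, min(1, 5 * out2$raw_p))
  expect_error(compareTHalf(list(a = 1, b = c(1, 2))), "2 replicates")
})

test_that("noise-free 4PL curves are recovered exactly", {
  d <- c(0, 0, 10^seq(-2, 1, length.out = 8))
  r <- fourPLResponse(d, 100, 0, 1, 1)
  fit <- fit4PL(d, r, n_boot = 0)
  expect_equal(ec50(fit), 1, tolerance = 0.01)
  expect_equal(fit@top, 100, tolerance = 0.1)
  expect_equal(fit@hill, 1, tolerance = 0.01)
  # dose-scale equivariance: scaling doses scales EC50
  fit2 <- fit4PL(d * 7, r, n_boot = 0)
  expect_equal(ec50(fit2) / ec50(fit), 7, tolerance = 1e-6)
  expect_error(fit4PL(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
})

test_that("flat responses raise the no-dose-dependence flag", {
  d <- c(0, 0, 10^seq(-2, 1, length.out = 8))
  set.seed(2)
  r <- 100 + rnorm(length(d), 0, 1)
  fit <- fit4PL(d, r, n_boot = 0)
  expect_true(fit@no_dose_dependence)
})

test_that("the bootstrap EC50 interval is seeded and calibrated", {
  pl <- normalizeToVehicle(simulateViabilityPlate(10^seq(-2, 1, length.out = 8),
                                                  cv = 0.05, seed = 12))
  f1 <- fit4PL(pl$dose, pl$response_pct, n_boot = 100, seed = 7)
  f2 <- fit4PL(pl$dose, pl$response_pct, n_boot = 100, seed = 7)
  expect_identical(f1@ci95_ec50, f2@ci95_ec50)
  expect_lt(f1@ci95_ec50[1], f1@ci95_ec50[2])
  # nominal-ish coverage of the true EC50 over several simulated plates
  cover <- 0L
  for (s in 1:10) {
    p <- normalizeToVehicle(simulateViabilityPlate(10^seq(-2, 1, length.out = 8),
                                                   cv = 0.05, seed = 100 + s))
    f <- fit4PL(p$dose, p$response_pct, n_boot = 60, seed = s)
    cover <- cover + (f@ci95_ec50[1] < 1 && f@ci95_ec50[2] > 1)
  }
  expect_gte(cover, 7L)
})

test_that("duplicated datasets give no evidence of a curve difference", {
  pl <- normalizeToVehicle(simulateViabilityPlate(10^seq(-2, 1, length.out = 8),
                                                  cv = 0.05, seed = 13))
  cmp <- compareDoseCurves(pl, pl)
  expect_lt(cmp$F, 1e-6)
  expect_gt(cmp$p, 0.99)
})

test_that("a large potency shift is detected", {
  a <- normalizeToVehicle(simulateViabilityPlate(10^seq(-2, 1, length.out = 8),
                                                 ec50 = 0.3, cv = 0.05,
                                                 seed = 14))
  b <- normalizeToVehicle(simulateViabilityPlate(10^seq(-2, 1, length.out = 8),
                                                 ec50 = 3, cv = 0.05,
                                                 seed = 15))
  expect_lt(compareDoseCurves(a, b)$p, 1e-4)
})
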