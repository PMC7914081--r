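test_that("zero-delay integration matches the logistic closed form and converges", {
  p <- delay_logistic_params(mu = 1, K = 100, x0 = 1)
  tr <- integrate_dde(p, horizon = 10, dt = 0.001)
  expect_equal(tr$value[tr$time == 5], logistic_closed_form(5, 1, 100, 1),
               tolerance = 1e-2)
  # error at least halves when dt halves (RK4 is far better than that)
  err_at <- function(dt) {
    tr <- integrate_dde(p, horizon = 10, dt = dt)
    max(abs(tr$value - logistic_closed_form(tr$time, 1, 100, 1)))
  }
  e1 <- err_at(0.02)
  e2 <- err_at(0.01)
  expect_lt(e2, e1 / 2 + 1e-12)
})

test_that("equilibria and degenerate parameters are fixed points", {
  for (taus in list(c(0, 0), c(2, 3))) {
    p <- delay_logistic_params(mu = 1, K = 50, tau1 = taus[1], tau2 = taus[2],
                               x0 = 50)
    tr <- integrate_dde(p, horizon = 20, dt = 0.1)
    expect_equal(tr$value, rep(50, nrow(tr)), tolerance = 1e-10)
  }
  p0 <- delay_logistic_params(mu = 1, K = 50, tau1 = 1, tau2 = 1, x0 = 0)
  expect_equal(integrate_dde(p0, 10, 0.1)$value, rep(0, 101))
  pz <- delay_logistic_params(mu = 0, K = 50, tau1 = 1, tau2 = 2, x0 = 7)
  expect_equal(integrate_dde(pz, 10, 0.1)$value, rep(7, 101))
})

test_that("integrator agrees with an independent DDE solver on a delayed case", {
  mu <- 0.8; K <- 1; tau1 <- 1; tau2 <- 2; x0 <- 0.1
  p <- delay_logistic_params(mu, K, tau1, tau2, x0)
  tr <- integrate_dde(p, horizon = 30, dt = 0.005)
  f <- function(t, y, parms) {
    x1 <- if (t - tau1 <= 0) x0 else deSolve::lagvalue(t - tau1)
    x2 <- if (t - tau2 <= 0) x0 else deSolve::lagvalue(t - tau2)
    list(mu * x1 * (1 - x2 / K))
  }
  ref <- deSolve::dede(y = x0, times = seq(0, 30, by = 0.1), func = f,
                       parms = NULL)
  ours <- tr$value[match(round(ref[, 1], 6), round(tr$time, 6))]
  expect_lt(max(abs(ours - ref[, 2])), 1e-4)
})

test_that("integrator rejects bad arguments and reports divergence", {
  p <- delay_logistic_params(mu = 1, K = 1, x0 = 0.1)
  expect_error(integrate_dde(p, horizon = -1, dt = 0.1), "horizon")
  expect_error(integrate_dde(p, horizon = 1, dt = 0), "dt")
  # extreme growth rate with delayed feedback overshoots the overflow guard
  pbad <- delay_logistic_params(mu = 1e5, K = 1, tau1 = 1, tau2 = 1, x0 = 0.5)
  expect_error(suppressWarnings(integrate_dde(pbad, 10, 0.5)),
               "diverged at step")
})

test_that("response classification follows the delay-driven regime progression", {
  mk <- function(tau2) {
    p <- delay_logistic_params(mu = 1, K = 1, tau1 = 0, tau2 = tau2, x0 = 0.1)
    integrate_dde(p, horizon = 60, dt = 0.01)
  }
  expect_identical(classify_response(mk(0), 1), "asymptotic_stabilization")
  expect_identical(classify_response(mk(0.3), 1), "asymptotic_stabilization")
  expect_identical(classify_response(mk(1.2), 1), "convergent_fluctuation")
  expect_identical(classify_response(mk(2.0), 1), "sustained_or_divergent")
  # constant trajectory at K has zero deviation
  const <- trajectory(seq(0, 10, 0.5), rep(3, 21))
  expect_identical(classify_response(const, 3), "asymptotic_stabilization")
  expect_error(classify_response(trajectory(1:5, rep(1, 5)), 1),
               "insufficient data")
})

test_that("specific growth rate matches the discrete estimator", {
  expect_equal(specific_growth_rate(trajectory(c(0, 1), c(100, 110))), 0.1)
  tt <- seq(0, 1, by = 0.01)
  expect_lt(abs(specific_growth_rate(trajectory(tt, exp(0.2 * tt))) - 0.2),
            1e-3)
  expect_equal(specific_growth_rate(trajectory(tt, rep(4, length(tt)))), 0)
  expect_error(specific_growth_rate(trajectory(c(0, 1, 2), c(1, 0, 1))),
               "positive")
})

test_that("identify_delays recovers generating delays on noiseless data", {
  pairs <- list(c(0, 0), c(2, 3), c(4.5, 7))
  for (tp in pairs) {
    p <- delay_logistic_params(mu = 0.5, K = 1, tau1 = tp[1], tau2 = tp[2],
                               x0 = 0.1)
    tr <- suppressWarnings(integrate_dde(p, horizon = 80, dt = 0.02))
    est <- suppressWarnings(
      identify_delays(tr, mu = 0.5, K = 1,
                      bounds = list(tau1 = c(0, 5), tau2 = c(0, 9)),
                      grid_n = 25))
    expect_lt(abs(est$tau1_hat - tp[1]), 0.05)
    expect_lt(abs(est$tau2_hat - tp[2]), 0.05)
    expect_true(est$tau1_ci[1] <= est$tau1_hat && est$tau1_hat <= est$tau1_ci[2])
  }
})

test_that("identify_delays flags a bound hit and rejects non-uniform grids", {
  p <- delay_logistic_params(mu = 0.5, K = 1, tau1 = 3, tau2 = 4, x0 = 0.1)
  tr <- integrate_dde(p, horizon = 60, dt = 0.05)
  est <- identify_delays(tr, mu = 0.5, K = 1,
                         bounds = list(tau1 = c(0, 2), tau2 = c(0, 9)),
                         grid_n = 12)
  expect_true(est$bound_hit)
  bad <- trajectory(c(0, 1, 3), c(1, 2, 3))
  expect_error(identify_delays(bad, mu = 0.5, K = 1), "uniform")
})

test_that("bootstrap intervals cover the generating delays under mild noise", {
  # scaled stand-in for the full Monte-Carlo coverage experiment: three
  # 1%-noise replicates, both delays covered in at least two of them
  set.seed(7)
  p <- delay_logistic_params(mu = 0.5, K = 1, tau1 = 2.45, tau2 = 5.29, x0 = 0.1)
  tr <- suppressWarnings(integrate_dde(p, horizon = 60, dt = 0.05))
  covered <- 0L
  for (rep in 1:3) {
    noisy <- trajectory(tr$time,
                        pmax(tr$value * (1 + rnorm(nrow(tr), 0, 0.01)), 0))
    est <- identify_delays(noisy, mu = 0.5, K = 1,
                           bounds = list(tau1 = c(0, 6), tau2 = c(0, 12)),
                           n_boot = 60, seed = 11 + rep, grid_n = 20)
    expect_lt(abs(est$tau1_hat - 2.45), 0.5)
    expect_lt(abs(est$tau2_hat - 5.29), 0.5)
    expect_true(est$tau1_ci[1] <= est$tau1_hat && est$tau1_hat <= est$tau1_ci[2])
    expect_true(est$tau2_ci[1] <= est$tau2_hat && est$tau2_hat <= est$tau2_ci[2])
    if (est$tau1_ci[1] <= 2.45 && 2.45 <= est$tau1_ci[2] &&
        est$tau2_ci[1] <= 5.29 && 5.29 <= est$tau2_ci[2])
      covered <- covered + 1L
  }
  expect_gte(covered, 2L)
})

test_that("series round-trip and taxon extraction work; parse errors are informative", {
  tmp <- tempfile(fileext = ".csv")
  df <- data.frame(time = 0:3, strepA = c(1, 2, 3, 4), prevB = c(4, 3, 2, 1))
  write_series(df, tmp)
  rd <- read_series(tmp)
  expect_equal(rd$strepA, c(1, 2, 3, 4))
  tr <- series_trajectory(rd, "prevB")
  expect_s3_class(tr, "trajectory")
  expect_error(series_trajectory(rd, "nope"), "strepA")
  writeLines(c("time,a", "0,1", "1,x"), tmp)
  expect_error(read_series(tmp), "row 2")
  writeLines("time,a", tmp)
  expect_error(read_series(tmp), "empty")
})
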