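test_that("quadratic interpolation recovers an exact parabola apex", {
  tt <- seq(0, 10, length.out = 201)
  y <- 100 - (tt - 3.37)^2 * 8
  traj <- structure(list(times = tt, prey = y + 200, predator = y + 100,
                         kind = "deterministic"), class = "lv_trajectory")
  pk <- extract_peaks(traj, n_peaks = 1)
  expect_equal(unname(pk["p1_prey_time"]), 3.37, tolerance = 1e-10)
  expect_equal(unname(pk["p1_prey_mag"]), 300, tolerance = 1e-10)
})

test_that("a monotone series has no interior peak", {
  tt <- seq(0, 10, length.out = 101)
  traj <- structure(list(times = tt, prey = exp(tt / 5) * 100,
                         predator = 50 + tt, kind = "deterministic"),
                    class = "lv_trajectory")
  expect_error(extract_peaks(traj, n_peaks = 1), "peak")
})

test_that("a sine peak is located to high accuracy", {
  tt <- seq(0, 10, length.out = 1001)
  y <- sin(2 * pi * tt / 10)
  traj <- structure(list(times = tt, prey = y + 2, predator = y + 2,
                         kind = "deterministic"), class = "lv_trajectory")
  pk <- extract_peaks(traj, n_peaks = 1)
  expect_lt(abs(pk["p1_prey_time"] - 2.5), 1e-4)
})

test_that("peak covariance equals the two-pass oracle and is PSD", {
  set.seed(88)
  runs <- matrix(rnorm(80, 10, 2), 10, 8,
                 dimnames = list(NULL, strucdisc:::peak_names(2)))
  sm <- fake_sample(setNames(rep(10, 8), colnames(runs)), runs)
  V <- peak_discrepancy_covariance(sm)
  k <- nrow(runs)
  m <- colMeans(runs)
  oracle <- matrix(0, 8, 8)
  for (i in 1:k)
    oracle <- oracle + tcrossprod(runs[i, ] - m)
  oracle <- oracle / (k - 1)
  expect_equal(unclass(V), oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)

  # identical runs give the zero matrix
  sm0 <- fake_sample(setNames(rep(1, 8), colnames(runs)),
                     matrix(5, 12, 8, dimnames = list(NULL, colnames(runs))))
  expect_true(all(peak_discrepancy_covariance(sm0) == 0))

  # excessive extraction failures are an error
  runs_na <- runs
  runs_na[1:3, 1] <- NA
  expect_error(peak_discrepancy_covariance(fake_sample(m, runs_na)), "10%")
})

test_that("covariance estimate converges at the Monte Carlo rate", {
  set.seed(17)
  A <- matrix(rnorm(64), 8)
  true_cov <- crossprod(A) + diag(8)
  L <- chol(true_cov)
  err <- vapply(c(50, 500, 5000), function(k) {
    runs <- matrix(rnorm(k * 8), k) %*% L
    colnames(runs) <- strucdisc:::peak_names(2)
    V <- peak_discrepancy_covariance(
      fake_sample(setNames(rep(0, 8), colnames(runs)), runs))
    norm(V - true_cov, "F")
  }, numeric(1))
  # one decade in k shrinks the error by roughly sqrt(10)
  expect_lt(err[3], err[1] / 3)
  expect_lt(err[2], err[1])
})

test_that("bayes linear adjustment matches hand-worked cases", {
  # no cross-covariance: the prior is returned unchanged
  cov0 <- diag(c(4, 9))
  bl0 <- bayes_linear_adjust(c(1, 2), cov0, z = 5)
  expect_equal(bl0$adjusted_mean, 2)
  expect_equal(drop(bl0$adjusted_cov), 9)

  # perfect correlation, no observation error: variance resolves to zero
  covp <- matrix(c(4, 4, 4, 4), 2)
  blp <- bayes_linear_adjust(c(0, 0), covp, z = 3)
  expect_equal(blp$adjusted_mean, 3)
  expect_equal(drop(blp$adjusted_cov), 0, tolerance = 1e-6)

  # printed two-variable fixture: cov [[4,2],[2,4]] + obs var 1 on the
  # historical block, prior means 0, z = 2
  cov2 <- matrix(c(4 + 1, 2, 2, 4), 2)
  bl2 <- bayes_linear_adjust(c(0, 0), cov2, z = 2)
  expect_equal(bl2$adjusted_mean, 0.8)
  expect_equal(drop(bl2$adjusted_cov), 3.2)
})

test_that("degenerate uncertainty collapses the forecast onto the simulator", {
  nm <- strucdisc:::peak_names(2)
  base <- setNames(c(2.5, 9000, 3.1, 7000, 7.5, 9000, 8.2, 7000), nm)
  runs <- matrix(rep(base, each = 20), 20, 8, dimnames = list(NULL, nm))
  sm <- fake_sample(base, runs)
  spec0 <- peak_uncertainty_spec(mag_ext_frac = 0, time_ext_sd = 0,
                                 mag_obs_sd = 0, time_obs_sd = 0)
  fc <- forecast_second_peak(sm, spec0, z_peaks = base[1:4])
  expect_equal(fc$naive_mean, base[5:8])
  expect_equal(fc$adjusted_mean, base[5:8], tolerance = 1e-6)
  expect_true(all(abs(fc$adjusted_cov) < 1e-6))
})

test_that("adjusted variances never exceed their naive counterparts", {
  res <- demo_result()
  for (fc in res$forecasts) {
    expect_true(all(diag(fc$adjusted_cov) <= diag(fc$naive_cov) + 1e-9))
    expect_gte(min(eigen(fc$resolved, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-6)
  }
})

test_that("peak ordering invariants hold for forecast inputs", {
  res <- demo_result()
  for (i in seq_len(min(10, length(res$forecasts)))) {
    b <- res$forecasts[[i]]$joint_cov
    expect_equal(dim(b), c(8, 8))
  }
  pk <- res$true_peaks
  expect_gt(pk["p2_prey_time"], pk["p1_prey_time"])
  expect_gt(pk["p2_pred_time"], pk["p1_pred_time"])
  expect_true(all(pk[grep("mag", names(pk))] > 0))
})
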