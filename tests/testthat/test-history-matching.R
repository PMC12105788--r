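test_that("implausibility is the standardized absolute distance", {
  # |E - z| = 30 with total variance 100 gives 3 standard deviations
  expect_equal(implausibility(130, 60, 0, 15, 100, 25), 3)
  expect_equal(implausibility(100, 50, 5, 25, 105, 25), 0)
  # scaling all variances by 4 halves the implausibility
  i1 <- implausibility(10, 4, 0, 3, 5, 2)
  i2 <- implausibility(10, 16, 0, 12, 5, 8)
  expect_equal(i2, i1 / 2)
  # the printed (non-square-rooted) variant
  expect_equal(implausibility(130, 60, 0, 15, 100, 25, squared = TRUE), 9)
  expect_error(implausibility(1, 0, 0, 0, 2, 0), "positive")
  expect_error(implausibility(1, -1, 0, 1, 2, 1), "non-negative")
})

test_that("maximum implausibility behaves like a maximum", {
  expect_equal(max_implausibility(c(0.1, 2.9, 1.0)), 2.9)
  expect_equal(max_implausibility(rep(1.7, 5)), 1.7)
  set.seed(2)
  for (r in 1:20) {
    v <- runif(sample(2:10, 1), 0, 5)
    expect_gte(max_implausibility(c(v, runif(1, 0, 5))),
               max_implausibility(v))
  }
  expect_error(max_implausibility(numeric(0)), "at least one")
})

test_that("inflating any variance term never increases implausibility", {
  set.seed(10)
  for (r in 1:50) {
    pm <- rnorm(1, 100, 30); z <- rnorm(1, 100, 30)
    vars <- runif(3, 1, 50)
    base <- implausibility(pm, vars[1], 0, vars[2], z, vars[3])
    bump <- runif(3, 0, 20)
    expect_lte(implausibility(pm, vars[1] + bump[1], 0, vars[2] + bump[2],
                              z, vars[3] + bump[3]), base)
  }
})

test_that("three-sigma coverage supports the threshold convention", {
  cov3 <- three_sigma_coverage()
  expect_true(all(cov3 >= 0.95))
  expect_equal(unname(cov3["gaussian"]), 2 * pnorm(3) - 1)
  expect_equal(unname(cov3["exponential"]), 1 - exp(-4))
  expect_equal(unname(cov3["uniform"]), 1)
})

toy_wave <- function(disc = discrepancy_spec("fractional"), threshold = 3,
                     frac = NULL) {
  if (!is.null(frac)) disc <- discrepancy_spec("fractional", fractional = frac)
  tr <- simulate_lvpp(mid_x())
  obs <- make_observations(tr, sigma_e = 50, seed = 8)
  d <- maximin_lhs(40, seed = 3)
  d[1, ] <- mid_x()  # include the generating point: a guaranteed match
  runs <- t(apply(d, 1, strucdisc:::run_on_grid))
  classify_wave(d, runs, obs, disc, threshold = threshold)
}

test_that("wave classification respects thresholds and discrepancy levels", {
  w <- toy_wave()
  expect_true(all(w$retained == (w$i_max <= 3)))
  expect_true(any(w$retained))  # data generated by an in-range model run

  # threshold zero retains (generically) nothing
  w0 <- toy_wave(threshold = 0)
  expect_equal(sum(w0$retained), 0)

  # enormous discrepancy retains everything
  whuge <- toy_wave(frac = 1e6)
  expect_true(all(whuge$retained))

  # retained sets are nested as the discrepancy level grows
  wlo <- toy_wave(frac = 0.05)
  whi <- toy_wave(frac = 0.15)
  expect_true(all(whi$i_max <= wlo$i_max + 1e-12))
  expect_true(all(which(wlo$retained) %in% which(whi$retained)))
})

test_that("refocusing re-accepts points satisfying the same criterion", {
  res <- demo_result()
  obs <- res$obs
  hist <- obs[obs$is_history, ]
  disc <- discrepancy_spec("fractional")
  # a retained point, re-tested under the same discrepancy, is re-retained
  x <- res$test_point
  f_out <- strucdisc:::run_on_grid(x)
  onames <- paste0(hist$species, "_t", hist$time)
  dm <- strucdisc:::discrepancy_moments(disc, x, f_out[onames])
  I <- implausibility(f_out[onames], 0, dm$mean, dm$var, hist$z,
                      hist$sigma_e^2)
  expect_lte(max_implausibility(I), 3)

  # an impossible acceptor exercises the failure path
  expect_error(
    refocus(res$wave1, disc, obs, function(p) strucdisc:::run_on_grid(p),
            n_target = 10, threshold = -1, seed = 1, max_draws = 300),
    "rate 0")
  # an empty previous retained set is an explicit failure
  empty <- res$wave1
  empty$retained <- FALSE
  expect_error(refocus(empty, disc, obs, identity), "empty")
})

test_that("wave-3 candidates re-pass the criterion that accepted them", {
  res <- demo_result()
  expect_gt(nrow(res$wave3), 0)
  obs <- res$obs
  hist <- obs[obs$is_history, ]
  onames <- paste0(hist$species, "_t", hist$time)
  n_check <- min(nrow(res$wave3), 15)
  ok <- vapply(seq_len(n_check), function(i) {
    x <- as.numeric(res$wave3[i, ])
    f_out <- strucdisc:::run_on_grid(x)[onames]
    dm <- strucdisc:::discrepancy_moments(res$disc2, x, f_out)
    I <- implausibility(f_out, 0, dm$mean, dm$var, hist$z, hist$sigma_e^2)
    max_implausibility(I) <= res$config$threshold
  }, logical(1))
  expect_true(all(ok))
})
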