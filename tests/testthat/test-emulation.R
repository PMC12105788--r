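make_design <- function(n, seed = 1, ranges = lvpp_ranges())
  maximin_lhs(n, ranges = ranges, seed = seed)

test_that("an exactly linear response is recovered with R^2 = 1", {
  d <- make_design(25)
  y <- 2 + 3 * d$x1 - 1000 * d$x2 + 0.5 * d$x3
  em <- fit_linear_emulator(d, y)
  expect_equal(unname(em$r_squared), 1, tolerance = 1e-10)
  expect_lt(em$sigma2, 1e-10)
  pr <- predict(em, c(1.0, 3e-4, 2.0))
  expect_equal(drop(pr$mean), 2 + 3 - 1000 * 3e-4 + 1, tolerance = 1e-6)
})

test_that("constant responses are flagged degenerate with R^2 = 0", {
  d <- make_design(20)
  em <- fit_linear_emulator(d, rep(7, 20))
  expect_equal(unname(em$r_squared), 0)
  expect_true(em$degenerate)
  expect_equal(unname(em$coefficients[-1, 1]), c(0, 0, 0), tolerance = 1e-9)
})

test_that("coefficients are recovered within three standard errors", {
  set.seed(44)
  truth <- c(5, 2, -1.5, 0.8)  # on the [-1, 1] coded scale
  hits <- 0
  reps <- 100
  for (r in 1:reps) {
    d <- make_design(40, seed = 400 + r)
    u <- 2 * strucdisc:::to_unit_cube(d, lvpp_ranges()) - 1
    y <- drop(cbind(1, u) %*% truth) + rnorm(40, 0, 0.5)
    em <- fit_linear_emulator(d, y)
    se <- sqrt(diag(em$xtx_inv) * em$sigma2)
    hits <- hits + all(abs(em$coefficients[, 1] - truth) <= 3 * se)
  }
  expect_gt(hits / reps, 0.9)
})

test_that("reported R^2 equals the direct residual-sum oracle", {
  set.seed(12)
  d <- make_design(30)
  y <- 3 * d$x1 + rnorm(30, 0, 0.3)
  em <- fit_linear_emulator(d, y)
  u <- 2 * strucdisc:::to_unit_cube(d, lvpp_ranges()) - 1
  fit <- lm(y ~ u)
  expect_equal(unname(em$r_squared), summary(fit)$r.squared,
               tolerance = 1e-10)
})

test_that("predictive variance is non-negative and flags extrapolation", {
  set.seed(3)
  d <- make_design(15)
  em <- fit_linear_emulator(d, rnorm(15))
  pts <- rbind(c(1, 3e-4, 1.8), c(0.71, 4e-5, 2.29), c(2.0, 3e-4, 1.8))
  pr <- predict(em, pts)
  expect_true(all(pr$var >= 0))
  expect_equal(pr$extrapolating, c(FALSE, FALSE, TRUE))
})

test_that("interpolating mode reproduces training data and matches GLS", {
  set.seed(21)
  n <- 10
  ranges <- list(x = c(0, 1))
  d <- structure(data.frame(x = sort(runif(n))), ranges = ranges,
                 class = c("design_matrix", "data.frame"))
  y <- sin(3 * d$x) + 0.2 * d$x
  theta <- 2
  em <- fit_linear_emulator(d, y, interpolate = TRUE, theta = theta)
  pr_train <- predict(em, as.matrix(d))
  expect_equal(drop(pr_train$mean), y, tolerance = 1e-5)

  # brute-force universal-kriging / GLS oracle via whitened regression
  u <- 2 * strucdisc:::to_unit_cube(d, ranges) - 1
  X <- cbind(1, u)
  K <- exp(-theta * outer(drop(u), drop(u), `-`)^2)
  diag(K) <- diag(K) + 1e-8
  L <- chol(K)
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  beta <- qr.coef(qr(Xw), yw)
  xnew <- seq(0.05, 0.95, by = 0.1)
  unew <- 2 * xnew - 1
  cc <- exp(-theta * outer(unew, drop(u), `-`)^2)
  oracle <- cbind(1, unew) %*% beta +
    cc %*% solve(K, y - X %*% beta)
  pr <- predict(em, matrix(xnew, ncol = 1))
  expect_equal(drop(pr$mean), drop(oracle), tolerance = 1e-8)
})

test_that("rank deficiency is reported with the collinear term named", {
  d <- make_design(12, ranges = list(x1 = c(0.7, 1.3), x2 = c(3.1e-5, 5.7e-4),
                                     x3 = c(1.3, 2.3)))
  d2 <- d
  d2$x3 <- d2$x1  # perfectly collinear after rescaling
  attr(d2, "ranges") <- list(x1 = c(0.7, 1.3), x2 = c(3.1e-5, 5.7e-4),
                             x3 = c(0.7, 1.3))
  expect_error(fit_linear_emulator(d2, rnorm(12)), "collinear")
})

test_that("internal-discrepancy augmentation behaves additively", {
  d <- make_design(20, seed = 9)
  zero_em <- fit_linear_emulator(d, matrix(0, 20, 2,
                                           dimnames = list(NULL, c("a", "b"))))
  b0_em <- fit_linear_emulator(d, matrix(c(rep(5, 20), rep(-2, 20)), 20, 2,
                                         dimnames = list(NULL, c("a", "b"))))
  base_fn <- function(x) c(a = sum(x), b = prod(x))
  x0 <- c(1, 3e-4, 2)

  aug0 <- predict_augmented(augment_with_internal(base_fn, zero_em, zero_em),
                            x0)
  expect_equal(aug0$mean, base_fn(x0))
  expect_equal(aug0$cov, matrix(0, 2, 2), ignore_attr = TRUE)

  # constant bias field shifts the mean by -bias everywhere
  augb <- predict_augmented(augment_with_internal(base_fn, b0_em, zero_em),
                            x0)
  expect_equal(unname(augb$mean - base_fn(x0)), c(-5, 2), tolerance = 1e-8)

  # augmentation never decreases total predictive variance
  sd_em <- fit_linear_emulator(d, matrix(abs(rnorm(40, 3)), 20, 2,
                                         dimnames = list(NULL, c("a", "b"))))
  augv <- predict_augmented(augment_with_internal(base_fn, zero_em, sd_em),
                            x0)
  expect_true(all(diag(augv$cov) >= 0))
})

test_that("augmented covariance reproduces the generating experiment", {
  res <- demo_result()
  co <- res$components$both
  x <- res$test_point
  hn <- historical_names()
  aug <- augment_with_internal(
    function(x) strucdisc:::run_on_grid(x)[hn],
    res$bias_em, res$sd_em, corr = co$correlation[hn, hn])
  pr <- predict_augmented(aug, x)
  # compare predicted sd with the experiment's sampled sd at the test point
  samp_sd <- co$sd[hn]
  ok <- !co$degenerate[hn]
  rel <- abs(sqrt(diag(pr$cov))[ok] - samp_sd[ok]) / samp_sd[ok]
  expect_lt(median(rel), 0.35)
})

test_that("direct reification preserves or inflates moments as specified", {
  d <- make_design(18, seed = 2)
  y <- 1 + d$x1 + rnorm(18, 0, 0.2)
  em <- fit_linear_emulator(d, y)
  x0 <- c(1, 3e-4, 2)

  same <- reify_emulator(em, reified_spec())
  expect_equal(predict(same, x0), predict(em, x0))

  infl <- reify_emulator(em, reified_spec(nu_var = 0.5))
  expect_equal(drop(predict(infl, x0)$mean), drop(predict(em, x0)$mean))
  expect_gt(drop(predict(infl, x0)$var), drop(predict(em, x0)$var))
  expect_equal(infl$sigma2, em$sigma2)

  indep <- reify_emulator(em, reified_spec(gamma = 0, delta = 1))
  expect_equal(unname(attr(indep, "residual_corr_with_base")), 0)
})
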