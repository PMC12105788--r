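test_that("degenerate perturbation spec gives only null perturbations", {
  spec <- perturbation_spec(5, "both", ic_sd = 0, c_mean = 0, c_sd = 0)
  ps <- sample_perturbations(spec, seed = 1)
  for (p in ps) {
    expect_equal(p$init, c(2000, 800))
    for (m in p$modulators)
      expect_equal(eval_modulator_for_test(m, seq(0, 10, by = 0.5)),
                   rep(1, 21))
  }
})

test_that("the sinusoidal modulator passes through 1 at its phase", {
  m <- modulator_sinusoidal(a = 4.9, b = 0.7, c = 0.08)
  expect_equal(eval_modulator_for_test(m, 4.9), 1)
})

test_that("perturbation draws follow the specified laws", {
  spec <- perturbation_spec(10000, "time_only")
  ps <- sample_perturbations(spec, seed = 42)
  cs <- vapply(ps, function(p) p$modulators[[1]]$pars[3], numeric(1))
  as <- vapply(ps, function(p) p$modulators[[1]]$pars[1], numeric(1))
  bs <- vapply(ps, function(p) p$modulators[[1]]$pars[2], numeric(1))
  expect_lt(abs(mean(cs) - 0.02), 3 * 0.05 / sqrt(10000))
  expect_lt(abs(sd(cs) / 0.05 - 1), 0.05)
  expect_true(all(as >= 4.5 & as <= 5.5))
  expect_true(all(bs >= 0.6 & bs <= 0.9))
  # time_only keeps initial conditions fixed
  expect_true(all(vapply(ps[1:50], function(p)
    identical(p$init, c(2000, 800)), logical(1))))
})

test_that("null perturbations reproduce the base run exactly", {
  spec <- perturbation_spec(3, "both", ic_sd = 0, c_mean = 0, c_sd = 0)
  sm <- run_discrepancy_experiment(mid_x(), sample_perturbations(spec, 1))
  for (j in seq_len(nrow(sm$runs)))
    expect_equal(unname(sm$runs[j, ]), unname(sm$base_run))
  su <- summarize_discrepancy(sm)
  expect_equal(unname(su$bias), rep(0, length(su$bias)))
  expect_equal(unname(su$variance), rep(0, length(su$variance)))
})

test_that("bias and variance summaries match the defining formulas", {
  # hand-worked two-run case: runs {10, 14}, base 11
  sm <- fake_sample(base = c(out = 11), runs = matrix(c(10, 14), ncol = 1,
                                                      dimnames = list(NULL, "out")))
  su <- summarize_discrepancy(sm)
  expect_equal(unname(su$bias), -1)
  expect_equal(unname(su$variance), 8)

  # against the brute-force estimator on a random fixture
  set.seed(31)
  runs <- matrix(rnorm(200 * 6, 50, 4), 200, 6,
                 dimnames = list(NULL, paste0("o", 1:6)))
  base <- rnorm(6, 50, 4)
  names(base) <- paste0("o", 1:6)
  su <- summarize_discrepancy(fake_sample(base, runs))
  k <- 200
  oracle_bias <- base - colSums(runs) / k
  oracle_var <- apply(runs, 2, function(col)
    sum((col - mean(col))^2) / (k - 1))
  expect_equal(su$bias, oracle_bias, tolerance = 1e-10)
  expect_equal(su$variance, oracle_var, tolerance = 1e-10)
  expect_equal(su$se_bias, sqrt(oracle_var / k), tolerance = 1e-10)
})

test_that("variance summary is unbiased for known Gaussian noise", {
  set.seed(7)
  sigma <- 3
  vs <- vapply(1:800, function(i) {
    runs <- matrix(rnorm(20, 0, sigma), ncol = 1,
                   dimnames = list(NULL, "o"))
    summarize_discrepancy(fake_sample(c(o = 0), runs))$variance
  }, numeric(1))
  se <- sd(vs) / sqrt(length(vs))
  expect_lt(abs(mean(vs) - sigma^2), 3 * se)
})

test_that("correlation handles exact linear dependence and degeneracy", {
  set.seed(5)
  a <- rnorm(50)
  runs <- cbind(o1 = a, o2 = 2 * a + 3, o3 = -a + 1, o4 = rep(4, 50))
  su <- summarize_discrepancy(fake_sample(c(o1 = 0, o2 = 0, o3 = 0, o4 = 4),
                                          runs))
  expect_equal(su$correlation["o1", "o2"], 1)
  expect_equal(su$correlation["o1", "o3"], -1)
  expect_true(su$degenerate[["o4"]])
  expect_true(all(is.na(su$correlation[, "o4"])))
  expect_false(anyNA(su$correlation[1:3, 1:3]))

  # symmetrized correlation is PSD to numerical tolerance
  cc <- su$correlation[1:3, 1:3]
  expect_gt(min(eigen((cc + t(cc)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values), -1e-10)
})

test_that("pooling decision distinguishes identical from varying fields", {
  set.seed(9)
  runs <- matrix(rnorm(100, 10, 2), 50, 2, dimnames = list(NULL, c("a", "b")))
  su <- summarize_discrepancy(fake_sample(c(a = 10, b = 10), runs))
  same <- pooled_or_varying(list(su, su, su))
  expect_equal(same$decision, "pool")
  expect_false(is.null(same$pooled))

  expect_error(pooled_or_varying(list(su)), ">= 2")
})

test_that("wave-2 discrepancy fields vary enough to require emulation", {
  res <- demo_result()
  expect_equal(pooled_or_varying(res$summaries)$decision, "emulate")
})

test_that("single-source variance components cannot exceed the joint total", {
  res <- demo_result()
  co <- res$components
  for (comp in c("ic", "time")) {
    v_comp <- co[[comp]]$variance
    tol <- 3 * (co$both$se_variance +
                  co[[comp]]$se_variance)
    expect_true(all(v_comp <= co$both$variance + tol))
  }
})
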