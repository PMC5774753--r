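test_that("simulated counts satisfy the type contract", {
  env <- simulate_env_series(env_params(innovation_sd = 1), seed = 1)
  cov <- sample_covariate(env, 200)
  y <- simulate_counts(cov, delta = 0, seed = 2)
  expect_s3_class(y, "count_series")
  expect_length(y$count, 200)
  expect_true(all(y$count >= 0))
  expect_true(all(y$count == round(y$count)))
  expect_equal(y$time, cov$age)
  # reproducible given the seed
  expect_identical(simulate_counts(cov, delta = 0, seed = 2)$count, y$count)
})

test_that("latent mean process is a martingale at its baseline", {
  # near-conjugate regime: the latent barely drifts, so the grand mean of
  # replicate simulations should sit at the baseline
  set.seed(8)
  means <- replicate(30, mean(simulate_counts(rep(0, 5000), delta = 0,
                                              omega = 0.99,
                                              baseline_mean = 10)$count))
  mc_se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 10), 3 * mc_se)
})

test_that("simulate then fit round-trips the generating parameters", {
  set.seed(9)
  est <- replicate(20, {
    x <- std_normal_covariate(200)
    y <- simulate_counts(x, delta = 0.5, omega = 0.6, baseline_mean = 100)
    f <- fit_pewma(y, matrix(x, ncol = 1))
    c(f$params$omega, f$params$delta)
  })
  expect_lt(abs(median(est[1, ]) - 0.6), 0.1)
  expect_lt(abs(median(est[2, ]) - 0.5), 0.1)
})

test_that("a zero correlation target needs no simulation at all", {
  env <- simulate_env_series(env_params(innovation_sd = 1), seed = 3)
  cov <- sample_covariate(env, 200)
  d <- calibrate_delta(cov, sim_design(0), seed = 1)
  expect_identical(as.numeric(d), 0)
  expect_identical(attr(d, "achieved_corr"), 0)
})

test_that("calibrated delta hits the target correlation on fresh batches", {
  env <- simulate_env_series(env_params(innovation_sd = 1), seed = 14)
  cov <- sample_covariate(env, 200)
  chron <- order(cov$age, decreasing = TRUE)
  xs <- as.numeric(scale(cov$value))[chron]
  design <- sim_design(0.5)
  d <- calibrate_delta(xs, design, seed = 77)
  expect_gte(as.numeric(d), 0)
  expect_lt(abs(attr(d, "achieved_corr") - 0.5), 0.02 + 1e-9)
  # fresh replicate batch, different seed
  set.seed(123456)
  fresh <- replicate(200, {
    y <- simulate_counts(xs, delta = as.numeric(d), omega = 0.6,
                         baseline_mean = 100)$count
    if (sd(y) == 0) 0 else cor(xs, y)
  })
  expect_lt(abs(median(fresh) - 0.5), 0.03)
})

test_that("achieved correlation is nondecreasing in delta under common draws", {
  env <- simulate_env_series(env_params(innovation_sd = 1), seed = 15)
  cov <- sample_covariate(env, 200)
  chron <- order(cov$age, decreasing = TRUE)
  xs <- as.numeric(scale(cov$value))[chron]
  med_cor <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(d) {
    set.seed(99)
    median(replicate(100, {
      y <- simulate_counts(xs, delta = d, omega = 0.6,
                           baseline_mean = 100)$count
      if (sd(y) == 0) 0 else cor(xs, y)
    }))
  }, numeric(1))
  expect_true(all(diff(med_cor) > -0.02))
  expect_gt(med_cor[5], med_cor[1])
})

test_that("unreachable targets raise a calibration failure", {
  env <- simulate_env_series(env_params(innovation_sd = 1), seed = 16)
  cov <- sample_covariate(env, 200)
  expect_error(
    calibrate_delta(cov, sim_design(0.9), seed = 1, n_rep = 50,
                    delta_max = 0.02),
    "calibration failure")
  expect_error(calibrate_delta(rep(1, 200), sim_design(0.5)),
               "non-constant")
})

test_that("null-delta correlations match the permutation null", {
  env <- simulate_env_series(env_params(innovation_sd = 1), seed = 17)
  cov <- sample_covariate(env, 200)
  chron <- order(cov$age, decreasing = TRUE)
  xs <- as.numeric(scale(cov$value))[chron]
  set.seed(18)
  y <- simulate_counts(xs, delta = 0, omega = 0.6, baseline_mean = 100)$count
  # permutation null of the correlation for THIS count realization
  obs <- replicate(300, cor(xs, simulate_counts(xs, delta = 0, omega = 0.6,
                                                baseline_mean = 100)$count))
  perm <- replicate(300, cor(xs, sample(y)))
  # both should be centred at zero; the simulated null is wider because the
  # latent random walk adds trend alignment on top of exchangeable noise
  expect_lt(abs(median(obs)), 0.15)
  expect_lt(abs(median(perm)), 0.05)
  expect_gte(quantile(abs(obs), 0.5), quantile(abs(perm), 0.5) - 0.02)
})
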