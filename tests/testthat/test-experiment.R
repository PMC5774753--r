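test_that("the hit rule is a strict AICc inequality with optional buffer", {
  expect_false(pewmachron:::is_hit(100, 100, 0))      # tie is not a hit
  expect_false(pewmachron:::is_hit(99, 100, 2))       # buffer not cleared
  expect_true(pewmachron:::is_hit(99, 100, 0))
  expect_true(pewmachron:::is_hit(97.9, 100, 2))
})

test_that("sub-pair analysis aligns, fits and scores one bootstrap draw", {
  set.seed(41)
  env <- simulate_env_series(env_params(innovation_sd = 1), seed = 41)
  cov <- sample_covariate(env, 100)
  counts <- simulate_counts(cov, delta = 0, seed = 42)
  res <- run_sub_pair(counts, env)
  expect_true(is.finite(res$aicc_cov) && is.finite(res$aicc_bench))
  expect_identical(res$hit,
                   res$valid && res$aicc_cov < res$aicc_bench)
  # disjoint calendar ranges are an error, not a silent misalignment
  shifted <- pewmachron:::new_env_series(env$age + 5000, env$value,
                                         env$position, env$params)
  expect_error(run_sub_pair(counts, shifted), "overlap")
})

test_that("top pairs are deterministic given their seed", {
  cfg <- experiment_config(corr = 0, innovation_sd = 1, n_dates = 5,
                           n_top = 1, n_boot = 6, seed = 1)
  a <- run_top_pair(cfg, 20240501L)
  b <- run_top_pair(cfg, 20240501L)
  expect_identical(a, b)
  expect_gte(a$hit_fraction, 0)
  expect_lte(a$hit_fraction, 1)
  expect_equal(a$n_valid + a$n_invalid, cfg$n_boot)
})

test_that("disabling chronological uncertainty collapses hit fractions to 0 or 1", {
  cfg <- experiment_config(corr = 0.5, innovation_sd = 1, n_dates = 5,
                           n_top = 4, n_boot = 7, seed = 2,
                           chrono_uncertainty = FALSE)
  d <- run_experiment(cfg)
  expect_length(d$hit_fractions, 4)
  expect_true(all(d$hit_fractions %in% c(0, 1)))
})

test_that("experiments run, stream to disk, resume, and reproduce", {
  cfg <- experiment_config(corr = 0, innovation_sd = 1, n_dates = 5,
                           n_top = 10, n_boot = 10, seed = 3)
  d1 <- run_experiment(cfg)
  expect_s3_class(d1, "hit_rate_distribution")
  expect_length(d1$hit_fractions, 10)
  expect_true(all(d1$hit_fractions >= 0 & d1$hit_fractions <= 1))
  # same master seed, identical distribution
  d2 <- run_experiment(cfg)
  expect_identical(d1$hit_fractions, d2$hit_fractions)
  # streaming + resumption: a partial results file is completed, rows kept
  path <- withr::local_tempfile(fileext = ".csv")
  cfg_small <- experiment_config(corr = 0, innovation_sd = 1, n_dates = 5,
                                 n_top = 3, n_boot = 5, seed = 4)
  run_experiment(cfg_small, results_path = path)
  full <- read.csv(path)
  expect_equal(nrow(full), 3)
  partial <- full[full$pair != 3, ]
  write.csv(partial, path, row.names = FALSE, quote = FALSE)
  resumed <- run_experiment(cfg_small, results_path = path)
  direct <- run_experiment(cfg_small)
  expect_equal(resumed$hit_fractions, direct$hit_fractions)
})

test_that("paper-scale bookkeeping enumerates the full factorial", {
  grid <- expand_experiment_grid()
  expect_length(grid, 36)
  key <- sapply(grid, function(g) paste(g$corr, g$innovation_sd, g$n_dates))
  expect_equal(anyDuplicated(key), 0L)

  cfg <- experiment_config(corr = 0, innovation_sd = 1, n_dates = 5,
                           n_top = 1000, n_boot = 2000)
  sched <- run_experiment(cfg, dry_run = TRUE)
  expect_identical(sched$n_subpairs, 2e6)

  expect_error(run_grid(list(grid[[1]], grid[[1]])), "duplicate")
})

test_that("a single-config grid reproduces run_experiment with provenance", {
  cfg <- experiment_config(corr = 0, innovation_sd = 1, n_dates = 5,
                           n_top = 4, n_boot = 5, seed = 6)
  g <- run_grid(list(cfg))
  d <- run_experiment(cfg)
  expect_equal(g$distributions[[1]]$hit_fractions, d$hit_fractions)
  tab <- g$table
  expect_true(all(c("corr", "innovation_sd", "n_dates", "n_top", "n_boot",
                    "aic_buffer", "seed", "lab_error", "omega",
                    "baseline_mean", "mode", "variance") %in% names(tab)))
  expect_equal(tab$corr, 0)
})

test_that("an infinite evidence buffer extinguishes every hit", {
  cfg <- experiment_config(corr = 0.5, innovation_sd = 1, n_dates = 5,
                           n_top = 2, n_boot = 5, seed = 7,
                           aic_buffer = 1e6)
  d <- run_experiment(cfg)
  expect_true(all(d$hit_fractions == 0))
})

test_that("hit-rate summaries report modes, variance and order-statistic quantiles", {
  s <- summarize_hit_rates(rep(0.10, 50))
  expect_lte(abs(s$mode - 0.10), 0.025)
  expect_equal(s$variance, 0)

  # constructed bimodal ensemble: bulk near 0.85, second cluster near 0.05
  set.seed(50)
  f <- c(pmin(pmax(rnorm(60, 0.85, 0.02), 0), 1),
         pmin(pmax(rnorm(30, 0.05, 0.015), 0), 1))
  s2 <- summarize_hit_rates(f)
  expect_lte(abs(s2$mode - 0.85), 0.05)
  expect_length(s2$secondary_modes, 1)
  expect_lte(abs(s2$secondary_modes - 0.05), 0.05)

  # quantiles are raw order statistics
  q <- summarize_hit_rates(f)$quantiles
  srt <- sort(f)
  oracle <- srt[ceiling(c(0.05, 0.25, 0.5, 0.75, 0.95) * length(f))]
  expect_equal(unname(q), oracle)

  # tie in bin counts resolves to the lower bin
  tied <- c(rep(0.32, 5), rep(0.62, 5))
  expect_equal(summarize_hit_rates(tied)$mode, 0.325)
})
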