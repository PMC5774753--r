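#' Configuration of one simulation experiment
#'
#' One experiment fixes a point of the study's free-parameter grid (target
#' correlation, environmental noise level, number of dated horizons) plus
#' the fixed design: span 12000-13000 cal BP, 200 count observations, 50-yr
#' lab error, discount factor 0.6, baseline mean 100, 1000 top-level pairs of
#' 2000 bootstrap sub-pairs each at full scale.
#'
#' @param corr target covariate-count correlation (0, 0.25, 0.5 or 0.75 in
#'   the study grid).
#' @param innovation_sd environmental AR(1) innovation sd (1, 0.1 or 0.01).
#' @param n_dates number of dated horizons (5, 15 or 25).
#' @param n_top number of top-level simulated pairs (full-scale value 1000).
#' @param n_boot chronological bootstrap sub-pairs per top pair (full-scale
#'   value 2000).
#' @param aic_buffer required AICc margin for a hit (default 0: strict
#'   inequality).
#' @param curve_source calibration curve: a `.14c` path, `fixture:<name>`
#'   tag or `cal_curve` object (see [resolve_curve()]).
#' @param seed master seed; per-pair seeds are derived from it.
#' @param span calendar span of the environmental series, cal BP.
#' @param n_samples covariate observations subsampled from the series.
#' @param lab_error 1-sigma lab error of the synthetic dates, 14C yr.
#' @param omega PEWMA discount factor used in count generation.
#' @param baseline_mean baseline latent mean of the count generator.
#' @param chrono_uncertainty if `FALSE`, sub-pairs use the true calendar
#'   timestamps instead of bootstrap age models (ablation diagnostic: every
#'   hit fraction is then exactly 0 or 1).
#' @param grid_step calibration grid step, calendar years.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(corr, innovation_sd, n_dates,
                              n_top = 1000, n_boot = 2000, aic_buffer = 0,
                              curve_source = "fixture:intcal_like",
                              seed = 1L, span = c(12000, 13000),
                              n_samples = 200, lab_error = 50, omega = 0.6,
                              baseline_mean = 100,
                              chrono_uncertainty = TRUE, grid_step = 1) {
  stopifnot(corr >= 0, corr < 1, innovation_sd >= 0, n_dates >= 2,
            n_top >= 1, n_boot >= 1, aic_buffer >= 0, n_samples >= 2,
            lab_error > 0)
  structure(list(corr = corr, innovation_sd = innovation_sd,
                 n_dates = as.integer(n_dates), n_top = as.integer(n_top),
                 n_boot = as.integer(n_boot), aic_buffer = aic_buffer,
                 curve_source = curve_source, seed = as.integer(seed),
                 span = sort(as.numeric(span)),
                 n_samples = as.integer(n_samples), lab_error = lab_error,
                 omega = omega, baseline_mean = baseline_mean,
                 chrono_uncertainty = isTRUE(chrono_uncertainty),
                 grid_step = grid_step),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> corr %.2f, innovation_sd %g, %d dates; %d pairs x %d bootstraps\n",
    x$corr, x$innovation_sd, x$n_dates, x$n_top, x$n_boot))
  invisible(x)
}

is_hit <- function(aicc_cov, aicc_bench, aic_buffer = 0) {
  aicc_cov < aicc_bench - aic_buffer
}

#' Analyse one bootstrap sub-pair
#'
#' The bootstrapped environmental values are linearly interpolated onto the
#' count series' calendar timestamps (clamped at the ends of the
#' bootstrapped age range), standardized and fitted as the single covariate
#' of a PEWMA regression; a constant-only PEWMA fit is the benchmark. The
#' covariate model scores a hit when its AICc beats the benchmark AICc by
#' more than `aic_buffer` (strictly).
#'
#' @param counts a [count_series()] with calendar timestamps.
#' @param env_boot an `env_series` carrying bootstrap (or true) calendar
#'   timestamps.
#' @param aic_buffer required AICc margin (default 0).
#' @param bench_fit optional precomputed constant-only `pewma_fit` for these
#'   counts (it does not depend on the bootstrap draw, so callers looping
#'   over draws fit it once).
#' @param ... passed on to [fit_pewma()].
#' @return list with `aicc_cov`, `aicc_bench`, `hit` and `valid`
#'   (convergence of both fits).
#' @export
run_sub_pair <- function(counts, env_boot, aic_buffer = 0,
                         bench_fit = NULL, ...) {
  stopifnot(inherits(counts, "count_series"),
            inherits(env_boot, "env_series"))
  if (min(env_boot$age) > max(counts$time) ||
      max(env_boot$age) < min(counts$time)) {
    stop("count and environmental series do not overlap in calendar time",
         call. = FALSE)
  }
  x <- stats::approx(env_boot$age, env_boot$value, xout = counts$time,
                     rule = 2)$y
  if (stats::sd(x) == 0) {
    return(list(aicc_cov = NA_real_, aicc_bench = NA_real_, hit = FALSE,
                valid = FALSE))
  }
  x_std <- as.numeric(scale(x))
  if (is.null(bench_fit)) bench_fit <- fit_pewma(counts, ...)
  fit_cov <- tryCatch(fit_pewma(counts, matrix(x_std, ncol = 1), ...),
                      error = function(e) NULL)
  if (is.null(fit_cov)) {
    return(list(aicc_cov = NA_real_, aicc_bench = bench_fit$aicc,
                hit = FALSE, valid = FALSE))
  }
  valid <- fit_cov$converged && bench_fit$converged
  list(aicc_cov = fit_cov$aicc, aicc_bench = bench_fit$aicc,
       hit = valid && is_hit(fit_cov$aicc, bench_fit$aicc, aic_buffer),
       valid = valid)
}

#' Run one top-level pair
#'
#' Simulates one environmental series and one PEWMA count series whose
#' regression coefficient is calibrated to the experiment's target
#' correlation, manufactures and calibrates the dated horizons, draws
#' `n_boot` order-constrained calendar-age vectors, and for each bootstrap
#' draw builds a monotone age model, re-timestamps the environmental
#' series and scores the sub-pair. Returns the fraction of valid sub-pairs
#' that were hits.
#'
#' @param config an [experiment_config()].
#' @param pair_seed integer seed for this pair; all randomness (environment,
#'   delta calibration, count generation, Gibbs draws) derives from it.
#' @return list with `hit_fraction`, `n_hits`, `n_valid`, `n_invalid`,
#'   `flagged` (`TRUE` when more than 10 percent of sub-pairs were invalid),
#'   `delta` and `achieved_corr`.
#' @export
run_top_pair <- function(config, pair_seed) {
  stopifnot(inherits(config, "experiment_config"))
  pair_seed <- as.integer(pair_seed)
  curve <- resolve_curve(config$curve_source)

  env <- simulate_env_series(
    env_params(span = config$span, innovation_sd = config$innovation_sd),
    seed = pair_seed)
  covariate <- sample_covariate(env, config$n_samples)

  design <- sim_design(config$corr, omega = config$omega,
                       baseline_mean = config$baseline_mean,
                       n_obs = config$n_samples)

  # The count process unfolds forward in time (oldest first, descending
  # cal BP); the filter is run in the same chronological order.
  chron <- order(covariate$age, decreasing = TRUE)
  x_std <- if (stats::sd(covariate$value) > 0)
    as.numeric(scale(covariate$value)) else covariate$value * 0
  ft_cov <- new_env_series(covariate$age[chron], x_std[chron],
                           covariate$position[chron], covariate$params)
  delta <- calibrate_delta(ft_cov, design, seed = pair_seed + 1L)
  counts <- simulate_counts(ft_cov, delta = as.numeric(delta),
                            omega = config$omega,
                            baseline_mean = config$baseline_mean,
                            seed = pair_seed + 2L)

  bench_fit <- tryCatch(fit_pewma(counts), error = function(e) NULL)
  if (is.null(bench_fit)) {
    # degenerate count realization (e.g. all zeros): whole pair invalid
    return(list(hit_fraction = NA_real_, n_hits = 0L, n_valid = 0L,
                n_invalid = config$n_boot, flagged = TRUE,
                delta = as.numeric(delta),
                achieved_corr = attr(delta, "achieved_corr")))
  }

  if (!config$chrono_uncertainty) {
    truth <- run_sub_pair(counts, env, config$aic_buffer, bench_fit)
    n_valid <- if (truth$valid) config$n_boot else 0L
    n_hits <- if (truth$valid && truth$hit) config$n_boot else 0L
    n_invalid <- config$n_boot - n_valid
  } else {
    horizons <- place_dated_horizons(config$span, config$n_dates)
    dates <- make_synthetic_c14_dates(curve, horizons$ages,
                                      lab_error = config$lab_error,
                                      positions = horizons$positions)
    densities <- lapply(dates, function(d)
      calibrate(curve, d, grid_step = config$grid_step))
    ages <- sample_ordered_calendar_ages(densities, n_draws = config$n_boot,
                                         seed = pair_seed + 3L)
    n_hits <- 0L
    n_valid <- 0L
    for (b in seq_len(config$n_boot)) {
      model <- build_age_model(horizons$positions, ages[b, ])
      env_boot <- new_env_series(apply_age_model(model, env$position),
                                 env$value, env$position, env$params)
      res <- run_sub_pair(counts, env_boot, config$aic_buffer, bench_fit)
      if (res$valid) {
        n_valid <- n_valid + 1L
        if (res$hit) n_hits <- n_hits + 1L
      }
    }
    n_invalid <- config$n_boot - n_valid
  }

  list(hit_fraction = if (n_valid > 0) n_hits / n_valid else NA_real_,
       n_hits = n_hits, n_valid = n_valid, n_invalid = n_invalid,
       flagged = n_invalid > 0.1 * config$n_boot,
       delta = as.numeric(delta),
       achieved_corr = attr(delta, "achieved_corr"))
}

derive_pair_seeds <- function(master_seed, n_top) {
  set.seed(master_seed)
  sample.int(2147483000L, n_top)
}

#' Run one experiment (all top-level pairs)
#'
#' Executes `n_top` independent top-level pairs with per-pair seeds derived
#' deterministically from the master seed, so any pair is reproducible in
#' isolation via [run_top_pair()]. When `results_path` is given, one result
#' row per pair is appended to a CSV as it completes, and an interrupted
#' run resumes from the rows already on disk.
#'
#' @param config an [experiment_config()].
#' @param results_path optional CSV path for incremental streaming and
#'   resumption.
#' @param dry_run if `TRUE`, do not simulate; return the bookkeeping
#'   schedule (number of top pairs, bootstraps, and total sub-pair
#'   analyses).
#' @param progress print a line per completed pair.
#' @return An object of class `hit_rate_distribution`: `hit_fractions`
#'   (one per top pair), `n_invalid`, `flagged`, `delta`, `achieved_corr`
#'   and the `config`. For `dry_run = TRUE`, a list with `n_top`, `n_boot`
#'   and `n_subpairs`.
#' @export
run_experiment <- function(config, results_path = NULL, dry_run = FALSE,
                           progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (dry_run) {
    return(list(n_top = config$n_top, n_boot = config$n_boot,
                n_subpairs = as.numeric(config$n_top) *
                  as.numeric(config$n_boot)))
  }
  seeds <- derive_pair_seeds(config$seed, config$n_top)
  done <- NULL
  if (!is.null(results_path) && file.exists(results_path)) {
    done <- utils::read.csv(results_path)
  }
  rows <- vector("list", config$n_top)
  for (i in seq_len(config$n_top)) {
    if (!is.null(done) && i %in% done$pair) {
      rows[[i]] <- done[done$pair == i, , drop = FALSE][1, ]
      next
    }
    r <- run_top_pair(config, seeds[i])
    row <- data.frame(pair = i, seed = seeds[i],
                      hit_fraction = r$hit_fraction, n_hits = r$n_hits,
                      n_valid = r$n_valid, n_invalid = r$n_invalid,
                      flagged = r$flagged, delta = r$delta,
                      achieved_corr = r$achieved_corr)
    rows[[i]] <- row
    if (!is.null(results_path)) {
      utils::write.table(row, results_path, sep = ",", append =
                           file.exists(results_path),
                         col.names = !file.exists(results_path),
                         row.names = FALSE, quote = FALSE)
    }
    if (progress) {
      message(sprintf("pair %d/%d: hit fraction %.3f", i, config$n_top,
                      r$hit_fraction))
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$pair), ]
  structure(list(hit_fractions = tab$hit_fraction,
                 n_invalid = tab$n_invalid, flagged = tab$flagged,
                 delta = tab$delta, achieved_corr = tab$achieved_corr,
                 config = config),
            class = "hit_rate_distribution")
}

#' @export
print.hit_rate_distribution <- function(x, ...) {
  s <- summarize_hit_rates(x)
  cat(sprintf(
    "<hit_rate_distribution> %d pairs; mode %.3f, median %.3f, variance %.4f\n",
    length(x$hit_fractions), s$mode, unname(s$quantiles["50%"]),
    s$variance))
  invisible(x)
}

#' Expand the study's factorial experiment grid
#'
#' Full factorial of the free parameters: by default 3 noise levels x 3
#' date counts x 4 correlations = 36 experiment configurations. Fixed
#' parameters are shared across the grid via `...`.
#'
#' @param innovation_sd noise levels.
#' @param n_dates dated-horizon counts.
#' @param corr target correlations.
#' @param ... fixed parameters forwarded to [experiment_config()].
#' @return list of [experiment_config()] objects.
#' @export
expand_experiment_grid <- function(innovation_sd = c(1, 0.1, 0.01),
                                   n_dates = c(5, 15, 25),
                                   corr = c(0, 0.25, 0.5, 0.75), ...) {
  grid <- expand.grid(corr = corr, n_dates = n_dates,
                      innovation_sd = innovation_sd)
  lapply(seq_len(nrow(grid)), function(i) {
    experiment_config(corr = grid$corr[i],
                      innovation_sd = grid$innovation_sd[i],
                      n_dates = grid$n_dates[i], ...)
  })
}

config_key <- function(cfg) {
  paste(cfg$corr, cfg$innovation_sd, cfg$n_dates, cfg$n_top, cfg$n_boot,
        cfg$aic_buffer, cfg$seed, sep = "|")
}

#' Run a grid of experiments
#'
#' One [run_experiment()] per configuration; duplicate configurations are
#' rejected. Returns the per-experiment distributions plus a summary table
#' carrying every free and fixed parameter.
#'
#' @param grid list of [experiment_config()] objects.
#' @param progress print a line per completed experiment.
#' @return list with `distributions` (list of `hit_rate_distribution`) and
#'   `table` (one summary row per experiment).
#' @export
run_grid <- function(grid, progress = FALSE) {
  stopifnot(is.list(grid), length(grid) >= 1L)
  keys <- vapply(grid, config_key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate experiment configurations in grid", call. = FALSE)
  }
  dists <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cfg <- grid[[i]]
    dists[[i]] <- run_experiment(cfg)
    s <- summarize_hit_rates(dists[[i]])
    rows[[i]] <- data.frame(
      corr = cfg$corr, innovation_sd = cfg$innovation_sd,
      n_dates = cfg$n_dates, n_top = cfg$n_top, n_boot = cfg$n_boot,
      aic_buffer = cfg$aic_buffer, seed = cfg$seed,
      span_lo = cfg$span[1], span_hi = cfg$span[2],
      n_samples = cfg$n_samples, lab_error = cfg$lab_error,
      omega = cfg$omega, baseline_mean = cfg$baseline_mean,
      mode = s$mode, variance = s$variance,
      median = unname(s$quantiles["50%"]),
      n_secondary_modes = length(s$secondary_modes))
    if (progress) {
      message(sprintf("experiment %d/%d done (mode %.3f)", i, length(grid),
                      s$mode))
    }
  }
  list(distributions = dists, table = do.call(rbind, rows))
}

#' Summarize a hit-rate distribution
#'
#' Histogram summary on `[0, 1]`: the primary mode is the midpoint of the
#' highest-count bin (ties broken toward the lower bin); secondary modes
#' are midpoints of non-adjacent bins whose count exceeds half the primary
#' bin's count. Quantiles are order statistics (type 1).
#'
#' @param dist a `hit_rate_distribution` or numeric vector of hit
#'   fractions in `[0, 1]`.
#' @param bin_width histogram bin width (default 0.05).
#' @return list with `mode`, `secondary_modes`, `variance`, `quantiles`
#'   (5, 25, 50, 75, 95 percent), `bin_counts` and `breaks`.
#' @export
summarize_hit_rates <- function(dist, bin_width = 0.05) {
  f <- if (inherits(dist, "hit_rate_distribution")) dist$hit_fractions
       else as.numeric(dist)
  f <- f[!is.na(f)]
  stopifnot(length(f) >= 1L, all(f >= 0 & f <= 1), bin_width > 0,
            bin_width <= 1)
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  nb <- length(breaks) - 1L
  bin <- pmin(findInterval(f, breaks, rightmost.closed = TRUE), nb)
  counts <- tabulate(bin, nbins = nb)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  primary <- which.max(counts)  # which.max takes the first (lower) tie
  sec <- which(counts > counts[primary] / 2 & abs(seq_len(nb) - primary) > 1)
  list(mode = mids[primary],
       secondary_modes = mids[sec],
       variance = if (length(f) > 1) stats::var(f) else 0,
       quantiles = stats::quantile(f, c(0.05, 0.25, 0.5, 0.75, 0.95),
                                   type = 1),
       bin_counts = counts, breaks = breaks, n = length(f))
}

#' Export sampled-age ensembles as delimited text
#' @param ages matrix from [sample_ordered_calendar_ages()] (one row per
#'   draw).
#' @param path output path; comma-separated, one row per draw.
#' @export
write_age_ensemble <- function(ages, path) {
  utils::write.table(as.data.frame(ages), path, sep = ",",
                     row.names = FALSE,
                     col.names = paste0("anchor_", seq_len(ncol(ages))),
                     quote = FALSE)
  invisible(path)
}
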