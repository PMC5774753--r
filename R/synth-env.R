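#' Parameters for the synthetic palaeoenvironmental generator
#'
#' The generator emulates a gently increasing environmental process observed
#' annually over a millennium: a linear signal plus stationary AR(1) noise.
#' Defaults are the fixed design of the simulation study: span 12000-13000
#' cal BP, slope 0.01 signal units per year, lag-1 autocorrelation 0.7, and
#' an annual grid of 1000 observations (start year inclusive). The
#' innovation standard deviation takes one of {1, 0.1, 0.01}; these map to
#' the categorical signal-to-noise labels {1, 10, 100}.
#'
#' @param span length-2 calendar interval, cal BP.
#' @param slope signal slope, units per calendar year.
#' @param phi AR(1) lag-1 autocorrelation, |phi| < 1.
#' @param innovation_sd AR(1) innovation standard deviation (>= 0).
#' @param n_points number of observations on the annual grid.
#' @return list of class `env_params`.
#' @export
env_params <- function(span = c(12000, 13000), slope = 0.01, phi = 0.7,
                       innovation_sd = 1, n_points = 1000) {
  stopifnot(length(span) == 2L, diff(range(span)) > 0, is.finite(slope),
            n_points >= 2L)
  if (abs(phi) >= 1) stop("|phi| must be < 1 (stationarity)", call. = FALSE)
  if (innovation_sd < 0) stop("innovation_sd must be >= 0", call. = FALSE)
  structure(list(span = sort(as.numeric(span)), slope = slope, phi = phi,
                 innovation_sd = innovation_sd, n_points = as.integer(n_points)),
            class = "env_params")
}

new_env_series <- function(age, value, position, params, provenance = list()) {
  structure(list(age = age, value = value, position = position,
                 params = params, provenance = provenance),
            class = "env_series")
}

#' @export
print.env_series <- function(x, ...) {
  cat(sprintf("<env_series> %d observations, %g-%g cal BP\n",
              length(x$age), min(x$age), max(x$age)))
  invisible(x)
}

#' Simulate a synthetic palaeoenvironmental series
#'
#' Observations are `slope * elapsed + e`, where `elapsed` is calendar years
#' since the series start (its oldest point) and `e` is a stationary AR(1)
#' path with autocorrelation `phi` and innovation standard deviation
#' `innovation_sd`, initialized from its stationary distribution (marginal
#' sd `innovation_sd / sqrt(1 - phi^2)`). The series lives on a regular
#' annual grid; ages are stored ascending in cal BP, with position 1 the
#' youngest observation (stationary Gaussian AR(1) noise is time-reversible,
#' so the storage direction carries no information).
#'
#' @param params an [env_params()].
#' @param seed optional integer seed.
#' @return An `env_series` with fields `age` (true calendar ages, cal BP),
#'   `value`, `position` (1-based grid index) and `params`.
#' @export
simulate_env_series <- function(params = env_params(), seed = NULL) {
  stopifnot(inherits(params, "env_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_points
  step <- 1
  age <- seq(params$span[1], by = step, length.out = n)
  elapsed <- max(age) - age
  signal <- params$slope * elapsed
  if (params$innovation_sd > 0) {
    marg_sd <- params$innovation_sd / sqrt(1 - params$phi^2)
    noise <- as.numeric(stats::filter(
      stats::rnorm(n, 0, params$innovation_sd), params$phi,
      method = "recursive", init = stats::rnorm(1, 0, marg_sd)))
  } else {
    noise <- numeric(n)
  }
  new_env_series(age, signal + noise, seq_len(n), params,
                 provenance = list(generator = "linear+ar1", seed = seed))
}

#' Evenly subsample an environmental series as a covariate
#'
#' Returns an evenly strided subsample including both endpoints, carrying
#' the corresponding true ages and positions. When `(n-1)/(n_samples-1)` is
#' not an integer the nearest-stride rule is applied (indices are the
#' rounded even spacing) and recorded in the provenance.
#'
#' @param env an `env_series`.
#' @param n_samples number of retained observations (2..length).
#' @return An `env_series` of length `n_samples`.
#' @export
sample_covariate <- function(env, n_samples) {
  stopifnot(inherits(env, "env_series"))
  n <- length(env$age)
  if (n_samples < 2L || n_samples > n) {
    stop("n_samples must be between 2 and length(env)", call. = FALSE)
  }
  idx <- round(seq(1, n, length.out = n_samples))
  strides <- diff(idx)
  new_env_series(env$age[idx], env$value[idx], env$position[idx],
                 env$params,
                 provenance = c(env$provenance,
                                list(subsample_n = n_samples,
                                     constant_stride =
                                       length(unique(strides)) == 1L)))
}

#' Place evenly spaced dated horizons over a span
#'
#' Calendar ages are evenly spaced across the span with both endpoints
#' included; positions are the corresponding fractional indices on the
#' annual grid anchored at the younger end of the span (position
#' `1 + (age - min(span)) / step`).
#'
#' @param span length-2 calendar interval, cal BP.
#' @param n_dates number of horizons (>= 2).
#' @param step grid step of the dated series in calendar years (default 1).
#' @return list with `positions` and `ages` (cal BP, ascending).
#' @export
place_dated_horizons <- function(span, n_dates, step = 1) {
  if (n_dates < 2L) stop("n_dates must be >= 2", call. = FALSE)
  stopifnot(length(span) == 2L, diff(range(span)) > 0, step > 0)
  ages <- seq(min(span), max(span), length.out = n_dates)
  list(positions = 1 + (ages - min(span)) / step, ages = ages)
}

#' Manufacture synthetic radiocarbon assays for known calendar ages
#'
#' Back-calibrates each true age through the curve and attaches a fixed
#' laboratory error (default +/- 50 radiocarbon years, a common lab
#' magnitude), producing the synthetic equivalent of uncalibrated
#' measurements returned by a dating laboratory.
#'
#' @param curve a [cal_curve()].
#' @param true_ages known calendar ages, cal BP (within the curve span).
#' @param lab_error 1-sigma laboratory error in radiocarbon years.
#' @param positions optional per-date positions (defaults to 1..n).
#' @return list of [c14_date()] objects, ordered as `true_ages`.
#' @export
make_synthetic_c14_dates <- function(curve, true_ages, lab_error = 50,
                                     positions = seq_along(true_ages)) {
  stopifnot(length(positions) == length(true_ages))
  c14 <- back_calibrate(curve, true_ages)
  lapply(seq_along(true_ages), function(i) {
    c14_date(c14[i], lab_error = lab_error, position = positions[i])
  })
}

#' Write an environmental series as delimited text
#'
#' `#`-prefixed provenance header (generator parameters) followed by
#' `age,position,value` rows.
#'
#' @param env an `env_series`.
#' @param path output path.
#' @export
write_env_series <- function(env, path) {
  stopifnot(inherits(env, "env_series"))
  con <- file(path, "w")
  on.exit(close(con))
  p <- env$params
  writeLines(c(
    "# env_series",
    sprintf("# span=%g:%g slope=%g phi=%g innovation_sd=%g n_points=%d",
            p$span[1], p$span[2], p$slope, p$phi, p$innovation_sd,
            p$n_points),
    "age,position,value"), con)
  writeLines(sprintf("%.10g,%.10g,%.15g", env$age, env$position, env$value),
             con)
  invisible(path)
}

#' Read an environmental series written by [write_env_series()]
#' @param path input path.
#' @return An `env_series` (parameters from the provenance header are not
#'   reconstructed; the data columns are).
#' @export
read_env_series <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("age", "position", "value") %in% names(df)))
  new_env_series(df$age, df$value, df$position, params = NULL,
                 provenance = list(source = path))
}
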