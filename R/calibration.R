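#' Calibration curves
#'
#' A calibration curve is a gridded mapping from calendar age (cal BP) to
#' conventional radiocarbon age (14C yr BP) together with the curve's own
#' 1-sigma error. Curves are always stored sorted ascending in cal BP.
#'
#' @param cal_age calendar ages, cal BP.
#' @param c14_age conventional radiocarbon ages, 14C yr BP, one per grid point.
#' @param error 1-sigma curve error in radiocarbon years, one per grid point.
#' @return An object of class `cal_curve` with fields `cal_age`, `c14_age`
#'   and `error`.
#' @export
cal_curve <- function(cal_age, c14_age, error) {
  cal_age <- as.numeric(cal_age)
  c14_age <- as.numeric(c14_age)
  error <- as.numeric(error)
  n <- length(cal_age)
  if (n < 2L || length(c14_age) != n || length(error) != n) {
    stop("calibration curve needs >= 2 grid points with aligned columns",
         call. = FALSE)
  }
  if (anyNA(cal_age) || anyNA(c14_age) || anyNA(error)) {
    stop("calibration curve contains missing values", call. = FALSE)
  }
  ord <- order(cal_age)
  cal_age <- cal_age[ord]
  c14_age <- c14_age[ord]
  error <- error[ord]
  if (any(diff(cal_age) <= 0)) {
    stop("calendar-age grid must be strictly monotone", call. = FALSE)
  }
  if (any(error < 0)) {
    stop("curve error must be non-negative", call. = FALSE)
  }
  structure(list(cal_age = cal_age, c14_age = c14_age, error = error),
            class = "cal_curve")
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf("<cal_curve> %d grid points, %s-%s cal BP\n",
              length(x$cal_age), format(min(x$cal_age)),
              format(max(x$cal_age))))
  invisible(x)
}

#' Read a calibration curve from a `.14c`-style text file
#'
#' Accepts the common three-column dialect: calendar age (cal BP),
#' radiocarbon age (14C BP) and 1-sigma curve error, with `#`-prefixed
#' comment lines and either comma or whitespace separation. Extra columns
#' (e.g. Delta-14C and its error) are ignored. Rows may appear in either
#' calendar order; the returned curve is sorted ascending in cal BP.
#'
#' @param path path to the curve file.
#' @param dialect column-order tag; only the standard
#'   `"calbp-c14-error"` order is defined.
#' @return A [cal_curve()].
#' @export
read_calibration_curve <- function(path, dialect = "calbp-c14-error") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) < 2L) {
    stop("calibration curve file has fewer than 2 data records",
         call. = FALSE)
  }
  parse_row <- function(line, lineno) {
    fields <- strsplit(trimws(line), "[,[:space:]]+")[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("line %d: expected >= 3 columns", lineno), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields[1:3]))
    if (anyNA(vals)) {
      stop(sprintf("line %d: malformed numeric field", lineno), call. = FALSE)
    }
    vals
  }
  recs <- t(vapply(seq_along(idx),
                   function(i) parse_row(lines[idx[i]], idx[i]),
                   numeric(3)))
  cal_curve(recs[, 1], recs[, 2], recs[, 3])
}

#' Write a calibration curve as delimited text
#'
#' Inverse of [read_calibration_curve()]: writes a `#` header comment plus
#' one comma-separated record per grid point, so that a written curve reads
#' back identically.
#'
#' @param curve a [cal_curve()].
#' @param path output path.
#' @export
write_calibration_curve <- function(curve, path) {
  stopifnot(inherits(curve, "cal_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cal BP, 14C age BP, 1-sigma error (yr)", con)
  writeLines(sprintf("%.10g,%.10g,%.10g",
                     curve$cal_age, curve$c14_age, curve$error), con)
  invisible(path)
}

#' Synthesize a wiggle calibration curve
#'
#' Deterministic analytic stand-in for a real calibration curve:
#' `c14(theta) = theta - base_offset + wiggle_amplitude * sin(2*pi*theta /
#' wiggle_period)` with a constant curve error. With amplitude zero and zero
#' offset this is the identity curve, on which calibration has a closed-form
#' Gaussian answer; with `2*pi*amplitude/period > 1` the curve is
#' non-invertible and produces multimodal calibrated densities, as real
#' curves do.
#'
#' @param span length-2 calendar interval (cal BP).
#' @param base_offset constant calendar-minus-radiocarbon offset, years.
#' @param wiggle_amplitude sinusoid amplitude, radiocarbon years.
#' @param wiggle_period sinusoid period, calendar years.
#' @param error_level constant 1-sigma curve error, radiocarbon years.
#' @param step grid step, calendar years.
#' @return A [cal_curve()].
#' @export
synthesize_curve <- function(span, base_offset = 0, wiggle_amplitude = 0,
                             wiggle_period = 500, error_level = 0,
                             step = 1) {
  if (length(span) != 2L || diff(range(span)) <= 0) {
    stop("span must be a nonempty interval", call. = FALSE)
  }
  if (step <= 0) stop("step must be positive", call. = FALSE)
  if (error_level < 0) stop("error_level must be >= 0", call. = FALSE)
  if (wiggle_amplitude != 0 && wiggle_period == 0) {
    stop("wiggle_period must be nonzero when wiggle_amplitude is nonzero",
         call. = FALSE)
  }
  theta <- seq(min(span), max(span), by = step)
  wig <- if (wiggle_amplitude == 0) 0 else
    wiggle_amplitude * sin(2 * pi * theta / wiggle_period)
  cal_curve(theta, theta - base_offset + wig, rep(error_level, length(theta)))
}

#' Resolve a curve source specification
#'
#' Accepts either a file path to a `.14c`-style curve or a `fixture:` tag
#' naming a built-in synthetic curve. Available fixtures:
#' \describe{
#'   \item{`fixture:identity`}{identity curve over 11500-13500 cal BP, zero
#'     error; calibration is then exactly Gaussian.}
#'   \item{`fixture:intcal_like`}{synthetic curve emulating the character of
#'     the early Younger Dryas portion of the international consensus curve:
#'     offset 1850 yr, 60-yr wiggles with a 500-yr period, constant 40-yr
#'     curve error, over 11500-13500 cal BP.}
#' }
#'
#' @param source path or `fixture:<name>` string, or a `cal_curve` (returned
#'   unchanged).
#' @return A [cal_curve()].
#' @export
resolve_curve <- function(source) {
  if (inherits(source, "cal_curve")) return(source)
  stopifnot(is.character(source), length(source) == 1L)
  if (grepl("^fixture:", source)) {
    name <- sub("^fixture:", "", source)
    switch(name,
      identity = synthesize_curve(c(11500, 13500)),
      intcal_like = synthesize_curve(c(11500, 13500), base_offset = 1850,
                                     wiggle_amplitude = 60,
                                     wiggle_period = 500, error_level = 40),
      stop("unknown curve fixture: ", name, call. = FALSE))
  } else {
    read_calibration_curve(source)
  }
}

#' Back-calibrate a calendar age
#'
#' Looks up the radiocarbon age corresponding to a known calendar age by
#' piecewise-linear interpolation of the curve; this is how synthetic
#' radiocarbon assays are manufactured from known ages.
#'
#' @param curve a [cal_curve()].
#' @param cal_age calendar age(s), cal BP; must lie within the curve span
#'   (no extrapolation).
#' @return radiocarbon age(s), 14C yr BP.
#' @export
back_calibrate <- function(curve, cal_age) {
  stopifnot(inherits(curve, "cal_curve"))
  rng <- range(curve$cal_age)
  if (any(cal_age < rng[1] | cal_age > rng[2])) {
    stop(sprintf("calendar age outside curve span [%g, %g]", rng[1], rng[2]),
         call. = FALSE)
  }
  stats::approx(curve$cal_age, curve$c14_age, xout = cal_age)$y
}

#' Construct a radiocarbon date
#'
#' @param c14_age measured radiocarbon age, 14C yr BP.
#' @param lab_error 1-sigma laboratory error, radiocarbon years; must be
#'   positive.
#' @param position sample position/depth/index in its series (non-negative).
#' @return An object of class `c14_date`.
#' @export
c14_date <- function(c14_age, lab_error = 50, position = 0) {
  if (!is.finite(c14_age)) stop("c14_age must be finite", call. = FALSE)
  if (!is.finite(lab_error) || lab_error <= 0) {
    stop("lab_error must be positive", call. = FALSE)
  }
  if (position < 0) stop("position must be non-negative", call. = FALSE)
  structure(list(c14_age = c14_age, lab_error = lab_error,
                 position = position), class = "c14_date")
}

#' Calibrate a radiocarbon date
#'
#' Standard gridded Gaussian-measurement calibration: the posterior mass at
#' calendar age theta is proportional to the normal density of the measured
#' radiocarbon age at mean `c14(theta)` with variance
#' `lab_error^2 + curve_error(theta)^2`, evaluated over the whole curve span
#' re-gridded at `grid_step`, then normalized to sum to one.
#'
#' @param curve a [cal_curve()].
#' @param date a [c14_date()].
#' @param grid_step calendar-year grid step for the returned density
#'   (default 1).
#' @return An object of class `cal_density` with fields `cal_age` (grid) and
#'   `mass` (probability per grid cell, summing to 1).
#' @export
calibrate <- function(curve, date, grid_step = 1) {
  stopifnot(inherits(curve, "cal_curve"), inherits(date, "c14_date"))
  if (grid_step <= 0) stop("grid_step must be positive", call. = FALSE)
  grid <- seq(min(curve$cal_age), max(curve$cal_age), by = grid_step)
  mu <- stats::approx(curve$cal_age, curve$c14_age, xout = grid)$y
  sig <- sqrt(date$lab_error^2 +
                stats::approx(curve$cal_age, curve$error, xout = grid)$y^2)
  w <- stats::dnorm(date$c14_age, mean = mu, sd = sig)
  tot <- sum(w)
  if (!is.finite(tot) || tot < 1e-300) {
    stop("date is incompatible with the calibration curve span",
         call. = FALSE)
  }
  structure(list(cal_age = grid, mass = w / tot,
                 position = date$position), class = "cal_density")
}

#' @export
print.cal_density <- function(x, ...) {
  m <- density_mean(x)
  cat(sprintf("<cal_density> %d grid points, mean %.1f cal BP\n",
              length(x$cal_age), m))
  invisible(x)
}

#' Mean of a calibrated density
#' @param density a `cal_density`.
#' @return mean calendar age, cal BP.
#' @export
density_mean <- function(density) {
  stopifnot(inherits(density, "cal_density"))
  sum(density$cal_age * density$mass)
}

#' Mode (maximum a posteriori grid point) of a calibrated density
#' @param density a `cal_density`.
#' @return calendar age of the highest-mass grid point, cal BP.
#' @export
density_mode <- function(density) {
  stopifnot(inherits(density, "cal_density"))
  density$cal_age[which.max(density$mass)]
}

#' Export a calibrated density as delimited text
#' @param density a `cal_density`.
#' @param path output path; one `cal_age,mass` row per grid point.
#' @export
write_density <- function(density, path) {
  stopifnot(inherits(density, "cal_density"))
  utils::write.table(
    data.frame(cal_age = density$cal_age, mass = density$mass),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
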