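# Shared fixtures and independent oracles, built in code at test time.

# Identity calibration curve: c14(theta) = theta, zero curve error.
identity_curve <- function(span = c(12000, 13000), step = 1) {
  synthesize_curve(span, base_offset = 0, wiggle_amplitude = 0,
                   error_level = 0, step = step)
}

# Gentle wiggle curve (invertible) used for generic calibration checks.
wiggle_curve <- function(span = c(11500, 13500)) {
  synthesize_curve(span, base_offset = 1850, wiggle_amplitude = 60,
                   wiggle_period = 500, error_level = 40)
}

# Strong wiggle curve: 2*pi*A/P > 1, non-invertible, multimodal densities.
folded_curve <- function(span = c(12000, 13000)) {
  synthesize_curve(span, base_offset = 0, wiggle_amplitude = 200,
                   wiggle_period = 500, error_level = 0)
}

# Independent oracle for the PEWMA predictive likelihood: numerical
# integration of the Poisson-Gamma mixture at every step, with the same
# conjugate bookkeeping but none of the closed-form negative binomial.
quadrature_loglik <- function(y, omega, a0, b0, m = rep(1, length(y))) {
  a <- a0
  b <- b0
  ll <- 0
  for (t in seq_along(y)) {
    a <- omega * a
    b <- omega * b
    f <- NULL
    for (rtol in c(1e-12, 1e-10, 1e-8)) {
      f <- tryCatch(stats::integrate(function(mu)
        stats::dpois(y[t], mu * m[t]) *
          stats::dgamma(mu, shape = a, rate = b),
        0, Inf, rel.tol = rtol)$value, error = function(e) NULL)
      if (!is.null(f)) break
    }
    ll <- ll + log(f)
    a <- a + y[t]
    b <- b + m[t]
  }
  ll
}

# Standardized iid normal covariate of length n (fast-varying, so the
# regression coefficient is well identified).
std_normal_covariate <- function(n) {
  as.numeric(scale(stats::rnorm(n)))
}

# Two-sample Kolmogorov-Smirnov statistic computed directly from the
# empirical CDFs (gridded ages produce heavy ties; this avoids relying on
# ks.test's tie handling).
ks_statistic <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(grid)
  Fy <- stats::ecdf(y)(grid)
  max(abs(Fx - Fy))
}
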