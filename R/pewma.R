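#' Count time-series
#'
#' A timestamped series of non-negative integer event counts (sites per
#' century, artefacts per layer, conflict events per interval, ...).
#'
#' @param time timestamps (calendar ages, cal BP, or any ordered axis).
#' @param count non-negative integer counts, aligned with `time`.
#' @return An object of class `count_series`.
#' @export
count_series <- function(time, count) {
  stopifnot(length(time) == length(count))
  check_counts(count)
  structure(list(time = as.numeric(time), count = as.integer(round(count))),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series> %d observations, mean count %.2f\n",
              length(x$count), mean(x$count)))
  invisible(x)
}

check_counts <- function(count) {
  if (length(count) == 0L || anyNA(count)) {
    stop("counts must be non-missing", call. = FALSE)
  }
  if (any(count < 0) || any(abs(count - round(count)) > 1e-8)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  invisible(TRUE)
}

as_count_vector <- function(counts) {
  if (inherits(counts, "count_series")) counts <- counts$count
  check_counts(counts)
  as.integer(round(counts))
}

as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates) || (is.matrix(covariates) && ncol(covariates) == 0L)) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  X <- as.matrix(covariates)
  if (nrow(X) != n) {
    stop("covariate rows must align one-to-one with counts", call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop("covariates must be finite", call. = FALSE)
  }
  X
}

#' PEWMA filter log-likelihood
#'
#' Runs the Poisson Exponentially Weighted Moving Average filter over a
#' count series and returns the one-step-ahead predictive log-likelihood and
#' the filtered Gamma-belief trajectory. At each step the Gamma belief
#' `(a, b)` about the latent positive mean is discounted (`a <- omega * a`,
#' `b <- omega * b`), the predictive mass for the observed count is the
#' Gamma-mixed Poisson, i.e. negative binomial with size `a` and success
#' probability `b / (b + m_t)` where `m_t = exp(base_rate + x_t . delta)`,
#' and the belief is updated conjugately (`a <- a + y_t`, `b <- b + m_t`).
#' Smaller `omega` discounts earlier observations faster, encoding stronger
#' autocorrelation decay; `omega = 1` reduces to standard conjugate
#' Poisson-Gamma updating.
#'
#' @param counts a [count_series()] or non-negative integer vector.
#' @param covariates numeric matrix aligned with `counts`, or `NULL`.
#' @param omega discount factor in (0, 1].
#' @param delta regression coefficient vector (one per covariate column).
#' @param base_rate constant per-step log drift of the mean process
#'   (default 0).
#' @param init length-2 vector `(a0, b0)`, both positive; defaults to
#'   `(mean(counts), 1)`.
#' @param skip number of initial predictive terms excluded from the
#'   log-likelihood sum (still filtered; default 0).
#' @return list with `loglik`, and `states` (data frame of filtered `a`,
#'   `b`, `latent_mean = a/b` and per-step `log_pred`).
#' @export
pewma_loglik <- function(counts, covariates = NULL, omega = 0.6,
                         delta = numeric(0), base_rate = 0, init = NULL,
                         skip = 0) {
  y <- as_count_vector(counts)
  X <- as_covariate_matrix(covariates, length(y))
  if (length(delta) != ncol(X)) {
    stop("delta must have one coefficient per covariate column",
         call. = FALSE)
  }
  if (omega <= 0 || omega > 1) stop("omega must be in (0, 1]", call. = FALSE)
  if (is.null(init)) init <- c(max(mean(y), 1e-8), 1)
  if (any(init <= 0)) stop("init (a0, b0) must be positive", call. = FALSE)
  res <- cpp_pewma_filter(y, X, omega, as.numeric(delta), base_rate,
                          init[1], init[2], as.integer(skip))
  list(loglik = res$loglik,
       states = data.frame(a = res$a, b = res$b,
                           latent_mean = res$latent_mean,
                           log_pred = res$log_pred))
}

#' Fit a PEWMA model by maximum likelihood
#'
#' Joint maximum-likelihood estimation of the discount factor `omega`
#' (logistic-transformed, bounded to (0.01, 1]) and the regression
#' coefficients `delta` (unbounded), by derivative-free Nelder-Mead search
#' on the transformed parameters. The predictive log-likelihood is
#' evaluated at each of the deterministic `omega` starts (with `delta = 0`)
#' and the search is polished from the best `n_polish` of them, guarding
#' against multimodality in `omega`.
#'
#' @inheritParams pewma_loglik
#' @param omega_starts deterministic starting values for the discount
#'   factor.
#' @param n_polish number of best-ranked starts polished by the full search.
#' @param maxit,tol Nelder-Mead iteration cap and relative
#'   function-convergence tolerance.
#' @return An object of class `pewma_fit`: `params` (`omega`, `delta`,
#'   `base_rate`), `loglik`, `n_obs`, `k` (number of covariate columns),
#'   `aicc`, `states` (filtered trajectory at the optimum) and `converged`.
#' @export
fit_pewma <- function(counts, covariates = NULL,
                      omega_starts = c(0.2, 0.4, 0.6, 0.8, 0.99),
                      n_polish = 2, base_rate = 0, init = NULL, skip = 0,
                      maxit = 500, tol = 1e-8) {
  y <- as_count_vector(counts)
  if (length(y) < 10L) {
    stop("need at least 10 observations to fit a PEWMA model",
         call. = FALSE)
  }
  if (all(y == 0L)) {
    stop("degenerate data: all counts are zero", call. = FALSE)
  }
  X <- as_covariate_matrix(covariates, length(y))
  if (is.null(init)) init <- c(mean(y), 1)
  res <- cpp_pewma_fit(y, X, omega_starts, base_rate, init[1], init[2],
                       as.integer(skip), as.integer(n_polish),
                       as.integer(maxit), tol)
  k <- ncol(X)
  n <- length(y)
  states <- pewma_loglik(y, if (k) X else NULL, omega = res$omega,
                         delta = res$delta, base_rate = base_rate,
                         init = init, skip = skip)$states
  structure(list(params = list(omega = res$omega,
                               delta = as.numeric(res$delta),
                               base_rate = base_rate),
                 loglik = res$loglik, n_obs = n, k = k,
                 aicc = aicc(res$loglik, k, n), states = states,
                 init = init, converged = isTRUE(res$converged)),
            class = "pewma_fit")
}

#' @export
print.pewma_fit <- function(x, ...) {
  cat(sprintf(
    "<pewma_fit> n = %d, k = %d\n  omega = %.4f%s\n  loglik = %.4f, AICc = %.4f%s\n",
    x$n_obs, x$k, x$params$omega,
    if (x$k) paste0(", delta = ",
                    paste(sprintf("%.4f", x$params$delta), collapse = ", "))
    else "",
    x$loglik, x$aicc,
    if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' Small-sample corrected AIC
#'
#' `(-2 * loglik) + 2 * k * n / (n - k - 1)`, where `k` is the number of
#' covariates and `n` the series length. The scaled penalty
#' `2 k n / (n - k - 1)` equals `2k + 2k(k + 1) / (n - k - 1)`, i.e. this
#' is the classic small-sample correction of the AIC; it inflates the
#' penalty for short series, which are typical of archaeological counts,
#' and converges to the plain AIC as `n` grows. Lower is better.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of covariates.
#' @param n number of observations; requires `n - k - 1 > 0`.
#' @return the criterion value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) {
    stop("AICc requires n - k - 1 > 0", call. = FALSE)
  }
  (-2 * loglik) + 2 * k * n / (n - k - 1)
}

#' Write a count series as delimited text
#' @param counts a [count_series()].
#' @param path output path; `timestamp,count` rows.
#' @export
write_count_series <- function(counts, path) {
  stopifnot(inherits(counts, "count_series"))
  utils::write.table(data.frame(timestamp = counts$time,
                                count = counts$count),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a count series written by [write_count_series()]
#' @param path input path.
#' @return A [count_series()].
#' @export
read_count_series <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("timestamp", "count") %in% names(df)))
  count_series(df$timestamp, df$count)
}

#' Export a fitted model as a flat key-value report
#' @param fit a `pewma_fit`.
#' @param path output path.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "pewma_fit"))
  kv <- c(sprintf("omega=%.10g", fit$params$omega),
          if (fit$k) sprintf("delta_%d=%.10g", seq_len(fit$k),
                             fit$params$delta),
          sprintf("base_rate=%.10g", fit$params$base_rate),
          sprintf("loglik=%.10g", fit$loglik),
          sprintf("aicc=%.10g", fit$aicc),
          sprintf("n_obs=%d", fit$n_obs),
          sprintf("k=%d", fit$k),
          sprintf("converged=%s", fit$converged))
  writeLines(kv, path)
  invisible(path)
}
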