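#' Order-constrained Gibbs sampling of calendar ages
#'
#' Draws joint samples of calendar ages for a sequence of calibrated dates
#' under the stratigraphic constraint that age must increase with position
#' (deeper/earlier position, older cal BP). Each Gibbs sweep updates every
#' date in position order by inverse-CDF sampling from its calibrated
#' density truncated to the open interval between its current neighbours,
#' with a minimum separation of one grid cell, so every returned vector is
#' strictly ordered. The chain is initialized at the per-date density modes,
#' repaired to an ordered configuration by sequential clamping.
#'
#' @param densities list of `cal_density` objects ordered by position.
#' @param n_draws number of retained joint draws.
#' @param burn_in discarded initial sweeps (default 100).
#' @param thin keep every `thin`-th sweep after burn-in (default 1).
#' @param seed optional integer seed for reproducibility.
#' @return numeric matrix, `n_draws` rows by `length(densities)` columns,
#'   each row a strictly increasing vector of calendar ages (cal BP).
#' @export
sample_ordered_calendar_ages <- function(densities, n_draws,
                                         burn_in = 100, thin = 1,
                                         seed = NULL) {
  stopifnot(length(densities) >= 1L, n_draws >= 1L, burn_in >= 0L,
            thin >= 1L)
  for (d in densities) stopifnot(inherits(d, "cal_density"))
  if (!is.null(seed)) set.seed(seed)
  k <- length(densities)
  grids <- lapply(densities, `[[`, "cal_age")
  cdfs <- lapply(densities, function(d) cumsum(d$mass))
  gaps <- vapply(grids, function(g) if (length(g) > 1) min(diff(g)) else 1,
                 numeric(1))
  supports <- lapply(densities, function(d) d$cal_age[d$mass > 0])

  # Feasibility: greedy earliest-feasible configuration. Choosing the
  # smallest admissible age at each position is complete for a chain of
  # pairwise ordering constraints, so failure here proves infeasibility.
  greedy <- numeric(k)
  prev <- -Inf
  for (i in seq_len(k)) {
    ok <- supports[[i]][supports[[i]] >= prev + ifelse(i == 1, 0, gaps[i])]
    if (length(ok) == 0L) {
      stop("no strictly ordered configuration of calendar ages is feasible",
           call. = FALSE)
    }
    greedy[i] <- ok[1]
    prev <- greedy[i]
  }

  # Initial state: density modes, clamped forward to restore ordering;
  # fall back to the greedy configuration if clamping runs off a grid.
  state <- vapply(densities, density_mode, numeric(1))
  if (k >= 2L) {
    for (i in 2:k) {
      need <- state[i - 1] + gaps[i]
      if (state[i] < need) {
        ok <- supports[[i]][supports[[i]] >= need]
        if (length(ok) == 0L) {
          state <- greedy
          break
        }
        state[i] <- ok[1]
      }
    }
  }

  draw_site <- function(i, lower, upper) {
    g <- grids[[i]]
    cdf <- cdfs[[i]]
    lo <- if (is.finite(lower)) findInterval(lower - 1e-9, g) + 1L else 1L
    hi <- if (is.finite(upper)) findInterval(upper + 1e-9, g) else length(g)
    if (lo > hi) return(NA_real_)
    c_lo <- if (lo == 1L) 0 else cdf[lo - 1L]
    c_hi <- cdf[hi]
    if (c_hi <= c_lo) return(NA_real_)
    u <- stats::runif(1, c_lo, c_hi)
    j <- findInterval(u, cdf) + 1L
    j <- min(max(j, lo), hi)
    g[j]
  }

  out <- matrix(NA_real_, nrow = n_draws, ncol = k)
  total <- burn_in + n_draws * thin
  kept <- 0L
  for (sweep in seq_len(total)) {
    for (i in seq_len(k)) {
      lower <- if (i == 1L) -Inf else state[i - 1] + gaps[i]
      upper <- if (i == k) Inf else state[i + 1] - gaps[i]
      cand <- draw_site(i, lower, upper)
      if (!is.na(cand)) state[i] <- cand
    }
    if (sweep > burn_in && (sweep - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      out[kept, ] <- state
    }
  }
  structure(out,
            positions = vapply(densities, function(d) {
              if (is.null(d$position)) NA_real_ else d$position
            }, numeric(1)))
}

#' Build a monotone age-depth model
#'
#' Monotonicity-preserving cubic Hermite interpolant (Fritsch-Carlson
#' slopes, via [stats::splinefun()] method `"monoH.FC"`) through dated
#' anchor horizons. The interpolant reproduces the anchors exactly and is
#' monotone between them, so a single ordered draw of anchor ages yields an
#' age model free of stratigraphic inversions.
#'
#' @param anchor_positions strictly increasing positions (depth/index).
#' @param anchor_ages calendar ages (cal BP), nondecreasing with position.
#' @return An object of class `age_model`.
#' @export
build_age_model <- function(anchor_positions, anchor_ages) {
  n <- length(anchor_positions)
  stopifnot(n >= 2L, length(anchor_ages) == n)
  if (any(diff(anchor_positions) <= 0)) {
    stop("anchor positions must be strictly increasing (no ties)",
         call. = FALSE)
  }
  if (any(diff(anchor_ages) < 0)) {
    stop("anchor ages must be ordered consistently with positions",
         call. = FALSE)
  }
  fun <- stats::splinefun(anchor_positions, anchor_ages, method = "monoH.FC")
  structure(list(anchor_positions = as.numeric(anchor_positions),
                 anchor_ages = as.numeric(anchor_ages),
                 interpolant = fun),
            class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("<age_model> %d anchors, positions [%g, %g], ages [%g, %g] cal BP\n",
              length(x$anchor_positions), min(x$anchor_positions),
              max(x$anchor_positions), min(x$anchor_ages),
              max(x$anchor_ages)))
  invisible(x)
}

#' Evaluate an age-depth model
#'
#' @param model an [build_age_model()] result.
#' @param positions query positions; must lie within the anchor span
#'   (no extrapolation).
#' @return calendar ages (cal BP) at the queried positions.
#' @export
apply_age_model <- function(model, positions) {
  stopifnot(inherits(model, "age_model"))
  rng <- range(model$anchor_positions)
  if (any(positions < rng[1] | positions > rng[2])) {
    stop(sprintf("position outside anchor span [%g, %g]", rng[1], rng[2]),
         call. = FALSE)
  }
  model$interpolant(positions)
}
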