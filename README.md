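# pewmachron

PEWMA count time-series regression under radiocarbon dating uncertainty.

## The problem

Archaeological count series (sites, artefacts, conflict events per
interval) and palaeoenvironmental proxy series are the raw material for
testing hypotheses about long-term human–environment interaction. Both
are non-stationary and autocorrelated, and the proxy series are usually
dated through calibrated radiocarbon ages whose uncertainties are large,
irregular and multimodal. `pewmachron` is for researchers who want to (a)
fit Poisson state-space regressions that respect the first problem, and
(b) measure — by simulation — how badly the second problem degrades the
regression's true-positive and false-positive behaviour.

## The model

The **Poisson Exponentially Weighted Moving Average (PEWMA)** model keeps
a Gamma(a, b) belief about the latent positive Poisson mean. Each step
the belief is discounted, a ← ωa, b ← ωb with ω ∈ (0, 1], which preserves
its mean but inflates its variance (exponential down-weighting of the
past); covariates act through a log-linear exposure m<sub>t</sub> =
exp(r + x<sub>t</sub>δ). The one-step-ahead predictive for y<sub>t</sub>
is negative binomial with size ωa and probability ωb/(ωb + m<sub>t</sub>),
and the update is conjugate: a ← ωa + y<sub>t</sub>, b ← ωb +
m<sub>t</sub>. `fit_pewma()` maximises the predictive likelihood jointly
over (ω, δ). Model comparison uses the small-sample corrected AIC,

    AICc = −2L + 2kN/(N − k − 1),

and a covariate model "hits" when its AICc is strictly below the
constant-only benchmark's (optionally by an evidence buffer).

Around the model sits a radiocarbon toolchain: `.14c` curve reading and
synthesis, gridded Gaussian calibration, back-calibration, an
order-constrained Gibbs sampler for stratigraphically ordered calendar
ages, and monotone (Fritsch–Carlson) age-depth splines. The experiment
engine (`run_experiment()`, `run_grid()`) simulates paired
environment/count series with a calibrated target correlation, bootstraps
the covariate's chronology, and reports the distribution of per-pair hit
fractions. See the vignette
(`vignettes/chronological-uncertainty.Rmd`) for the full design.

## Worked example

```r
library(pewmachron)

# calibrate a synthetic assay on the packaged (synthetic) wiggle curve
curve <- read_calibration_curve(
  system.file("extdata", "synthetic_wiggle_curve.14c", package = "pewmachron"))
dens <- calibrate(curve, c14_date(10650, lab_error = 50))
dens
#> <cal_density> 1001 grid points, mean 12500.0 cal BP

# simulate a proxy series, drive a count series from it, and fit
env <- simulate_env_series(env_params(innovation_sd = 0.1), seed = 42)
covariate <- sample_covariate(env, 200)
y <- simulate_counts(as.numeric(scale(covariate$value)), delta = 0.3,
                     omega = 0.6, baseline_mean = 100, seed = 43)
fit <- fit_pewma(y, matrix(scale(covariate$value), ncol = 1))
fit
#> <pewma_fit> n = 200, k = 1
#>   omega = 0.5862, delta = 0.2851
#>   loglik = -812.1760, AICc = 1626.3722
bench <- fit_pewma(y)
fit$aicc < bench$aicc     # covariate model beats the constant-only benchmark
#> TRUE
```

The fitted discount factor (0.59) and coefficient (0.29) recover the
generating values (0.6, 0.3); the 16-point AICc margin over the benchmark
(1642.84 vs 1626.37) is a hit.

A small experiment — 10 simulated pairs, each chronologically
bootstrapped 50 times at target correlation 0.5 with noisy proxies:

```r
cfg <- experiment_config(corr = 0.5, innovation_sd = 1, n_dates = 5,
                         n_top = 10, n_boot = 50, seed = 1)
dist <- run_experiment(cfg)
round(dist$hit_fractions, 2)
#>  [1] 0.22 0.22 0.50 0.18 0.24 0.14 0.20 0.18 0.32 0.24
summarize_hit_rates(dist)$mode
#> [1] 0.225
```

Each number is the fraction of one pair's bootstrap sub-pairs in which
the covariate model beat its benchmark; that the fractions are strictly
between 0 and 1 is itself the signature of chronological uncertainty
(disable it with `chrono_uncertainty = FALSE` and every fraction becomes
exactly 0 or 1).

A command-line front end over the same functions is installed at
`inst/cli/pewmachron.R` (subcommands `simulate-env`, `calibrate-dates`,
`sample-ages`, `run-experiment`, `run-grid`, `summarize`).

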