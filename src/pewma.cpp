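#include <Rcpp.h>
using namespace Rcpp;

// Gamma-Poisson (PEWMA) filter. The Gamma belief (a, b) about the latent
// positive mean is discounted by omega each step, the one-step-ahead
// predictive for y_t is then negative binomial with size a and success
// probability b / (b + m_t), where m_t = exp(r + x_t . delta) is the
// log-linear exposure, and the belief is updated conjugately.

static inline double exposure_at(const NumericMatrix& X,
                                 const NumericVector& delta,
                                 double base_rate, int t) {
  double eta = base_rate;
  for (int j = 0; j < X.ncol(); ++j) eta += X(t, j) * delta[j];
  return std::exp(eta);
}

// [[Rcpp::export]]
List cpp_pewma_filter(IntegerVector y, NumericMatrix X, double omega,
                      NumericVector delta, double base_rate,
                      double a0, double b0, int skip) {
  const int n = y.size();
  NumericVector a_out(n), b_out(n), mean_out(n), pred_out(n);
  double a = a0, b = b0, ll = 0.0;
  for (int t = 0; t < n; ++t) {
    a *= omega;
    b *= omega;
    double m = exposure_at(X, delta, base_rate, t);
    double lp = R::dnbinom(y[t], a, b / (b + m), 1);
    pred_out[t] = lp;
    if (t >= skip) ll += lp;
    a += y[t];
    b += m;
    a_out[t] = a;
    b_out[t] = b;
    mean_out[t] = a / b;
  }
  return List::create(_["loglik"] = ll, _["a"] = a_out, _["b"] = b_out,
                      _["latent_mean"] = mean_out, _["log_pred"] = pred_out);
}

// [[Rcpp::export]]
double cpp_pewma_loglik(IntegerVector y, NumericMatrix X, double omega,
                        NumericVector delta, double base_rate,
                        double a0, double b0, int skip) {
  const int n = y.size();
  double a = a0, b = b0, ll = 0.0;
  for (int t = 0; t < n; ++t) {
    a *= omega;
    b *= omega;
    double m = exposure_at(X, delta, base_rate, t);
    if (t >= skip) ll += R::dnbinom(y[t], a, b / (b + m), 1);
    a += y[t];
    b += m;
  }
  return ll;
}

// Reverse filter: draw the latent mean from the discounted Gamma belief
// (equivalent to applying the Beta(omega*a, (1-omega)*a) multiplicative
// shock of the transition equation), emit a Poisson count with the
// covariate exposure applied, then update the belief as the filter would.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_pewma_simulate(NumericMatrix X, double omega, NumericVector delta,
                        double base_rate, double a0, double b0) {
  const int n = X.nrow();
  IntegerVector y(n);
  NumericVector mu_star(n), lambda(n);
  double a = a0, b = b0;
  for (int t = 0; t < n; ++t) {
    a *= omega;
    b *= omega;
    double m = exposure_at(X, delta, base_rate, t);
    double mu = R::rgamma(a, 1.0 / b); // shape, scale
    double lam = mu * m;
    y[t] = (int)R::rpois(lam);
    mu_star[t] = mu;
    lambda[t] = lam;
    a += y[t];
    b += m;
  }
  return List::create(_["counts"] = y, _["mu_star"] = mu_star,
                      _["lambda"] = lambda);
}

// ---- maximum-likelihood fitting -------------------------------------------
// omega is optimised on a logistic transform bounded to (omega_lo, 1];
// delta is unbounded. Derivative-free Nelder-Mead on the joint vector.

static const double OMEGA_LO = 0.01;

static inline double omega_from_t(double t) {
  return OMEGA_LO + (1.0 - OMEGA_LO) / (1.0 + std::exp(-t));
}
static inline double t_from_omega(double w) {
  double p = (w - OMEGA_LO) / (1.0 - OMEGA_LO);
  p = std::min(std::max(p, 1e-9), 1.0 - 1e-9);
  return std::log(p / (1.0 - p));
}

struct PewmaObjective {
  const IntegerVector& y;
  const NumericMatrix& X;
  double base_rate, a0, b0;
  int skip;
  long evals;
  PewmaObjective(const IntegerVector& y_, const NumericMatrix& X_,
                 double r, double a0_, double b0_, int skip_)
      : y(y_), X(X_), base_rate(r), a0(a0_), b0(b0_), skip(skip_), evals(0) {}
  // par = (t_omega, delta...)
  double operator()(const std::vector<double>& par) {
    ++evals;
    double w = omega_from_t(par[0]);
    NumericVector d(par.size() - 1);
    for (size_t j = 1; j < par.size(); ++j) d[j - 1] = par[j];
    double ll = cpp_pewma_loglik(y, X, w, d, base_rate, a0, b0, skip);
    if (!std::isfinite(ll)) return 1e100;
    return -ll;
  }
};

// Plain Nelder-Mead; adequate for the 1-2 free parameters used here.
static bool nelder_mead(PewmaObjective& f, std::vector<double>& x,
                        double& fx, int maxit, double tol) {
  const int d = (int)x.size();
  const int np = d + 1;
  std::vector<std::vector<double> > S(np, x);
  std::vector<double> fv(np);
  for (int i = 0; i < d; ++i) S[i + 1][i] += (i == 0 ? 0.6 : 0.3);
  for (int i = 0; i < np; ++i) fv[i] = f(S[i]);

  for (int it = 0; it < maxit; ++it) {
    // order
    for (int i = 0; i < np; ++i)
      for (int j = i + 1; j < np; ++j)
        if (fv[j] < fv[i]) { std::swap(fv[i], fv[j]); std::swap(S[i], S[j]); }
    if (std::fabs(fv[np - 1] - fv[0]) < tol * (std::fabs(fv[0]) + tol)) {
      x = S[0]; fx = fv[0];
      return true;
    }
    std::vector<double> cen(d, 0.0);
    for (int i = 0; i < np - 1; ++i)
      for (int j = 0; j < d; ++j) cen[j] += S[i][j] / (np - 1);
    std::vector<double> xr(d), xe(d), xc(d);
    for (int j = 0; j < d; ++j) xr[j] = cen[j] + (cen[j] - S[np - 1][j]);
    double fr = f(xr);
    if (fr < fv[0]) {
      for (int j = 0; j < d; ++j) xe[j] = cen[j] + 2.0 * (cen[j] - S[np - 1][j]);
      double fe = f(xe);
      if (fe < fr) { S[np - 1] = xe; fv[np - 1] = fe; }
      else         { S[np - 1] = xr; fv[np - 1] = fr; }
    } else if (fr < fv[np - 2]) {
      S[np - 1] = xr; fv[np - 1] = fr;
    } else {
      for (int j = 0; j < d; ++j) xc[j] = cen[j] + 0.5 * (S[np - 1][j] - cen[j]);
      double fc = f(xc);
      if (fc < fv[np - 1]) { S[np - 1] = xc; fv[np - 1] = fc; }
      else {
        for (int i = 1; i < np; ++i) {
          for (int j = 0; j < d; ++j) S[i][j] = S[0][j] + 0.5 * (S[i][j] - S[0][j]);
          fv[i] = f(S[i]);
        }
      }
    }
  }
  int best = 0;
  for (int i = 1; i < np; ++i) if (fv[i] < fv[best]) best = i;
  x = S[best]; fx = fv[best];
  return false;
}

// Multi-start MLE: the negative log-likelihood is evaluated at every
// requested omega start (delta = 0); full Nelder-Mead polishing is run from
// the best `n_polish` distinct starts and the overall optimum returned.
// [[Rcpp::export]]
List cpp_pewma_fit(IntegerVector y, NumericMatrix X,
                   NumericVector omega_starts, double base_rate,
                   double a0, double b0, int skip, int n_polish,
                   int maxit, double tol) {
  const int k = X.ncol();
  PewmaObjective obj(y, X, base_rate, a0, b0, skip);

  const int ns = omega_starts.size();
  std::vector<double> start_f(ns);
  std::vector<std::vector<double> > start_x(ns);
  for (int s = 0; s < ns; ++s) {
    std::vector<double> par(1 + k, 0.0);
    par[0] = t_from_omega(omega_starts[s]);
    start_x[s] = par;
    start_f[s] = obj(par);
  }
  std::vector<int> ord(ns);
  for (int s = 0; s < ns; ++s) ord[s] = s;
  std::sort(ord.begin(), ord.end(),
            [&](int i, int j) { return start_f[i] < start_f[j]; });

  int npol = std::min(std::max(n_polish, 1), ns);
  std::vector<double> best_x;
  double best_f = R_PosInf;
  bool best_conv = false;
  for (int s = 0; s < npol; ++s) {
    std::vector<double> x = start_x[ord[s]];
    double fx;
    bool conv = nelder_mead(obj, x, fx, maxit, tol);
    if (fx < best_f) { best_f = fx; best_x = x; best_conv = conv; }
  }

  double w = omega_from_t(best_x[0]);
  NumericVector delta(k);
  for (int j = 0; j < k; ++j) delta[j] = best_x[j + 1];
  return List::create(_["omega"] = w, _["delta"] = delta,
                      _["loglik"] = -best_f, _["converged"] = best_conv,
                      _["n_evals"] = (double)obj.evals);
}
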