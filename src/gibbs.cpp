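#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Floors guarding conditionals that are improper at exactly zero; such values
// occur with probability zero in theory but do arise in floating point.
static const double RESID2_FLOOR = 1e-12;
static const double COEF_FLOOR = 1e-10;

// Inverse-Gaussian(mean mu, shape lambda) sampler, Michael-Schucany-Haas.
// Density ~ x^{-3/2} exp(-lambda (x - mu)^2 / (2 mu^2 x)).
static double rinvgauss1(double mu, double lambda) {
  double nu = norm_rand();
  double y = nu * nu;
  double x = mu + 0.5 * mu * mu * y / lambda -
             (0.5 * mu / lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0 || !std::isfinite(x)) x = RESID2_FLOOR; // numeric underflow guard
  double u = unif_rand();
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// Spike probability l = pi / (pi + (1-pi) * sqrt(var/slab_var) * exp(mean^2/(2 var))),
// computed in log space so large mean^2/var never overflows.
static double spike_prob(double mean, double var, double slab_var, double pi) {
  if (pi <= 0.0) return 0.0;
  if (pi >= 1.0) return 1.0;
  double log_bf = 0.5 * std::log(var / slab_var) + 0.5 * mean * mean / var;
  // l = 1 / (1 + exp(log((1-pi)/pi) + log_bf))
  double t = std::log1p(-pi) - std::log(pi) + log_bf;
  if (t > 700.0) return 0.0;
  return 1.0 / (1.0 + std::exp(t));
}

// Draw from the two-component conditional; consumes one uniform and, when the
// slab is chosen, one normal variate. With pi fixed at 0 this is exactly the
// plain Bayesian-LASSO slab draw (the uniform is still consumed so that
// sparse-with-pi-0 and non-sparse runs are draw-for-draw identical).
static double spike_slab_draw(double mean, double var, double l, int& ind) {
  double u = unif_rand();
  if (u < l) {
    ind = 0;
    return 0.0;
  }
  ind = 1;
  return mean + std::sqrt(var) * norm_rand();
}

// s | coef: Exponential(rate phi^2/2) at the spike, otherwise
// 1/s ~ Inverse-Gaussian(sqrt(phi^2/coef^2), phi^2).
static double slab_variance_draw(double coef, double phisq) {
  if (coef == 0.0) return R::rexp(2.0 / phisq);
  double c = std::max(std::fabs(coef), COEF_FLOOR);
  double mu = std::sqrt(phisq) / c;
  return 1.0 / rinvgauss1(mu, phisq);
}

struct Hyper {
  double a, b, c1, d1, c2, d2, r1, u1, r2, u2, alpha0, gamma0, xi2sq, sigma_a, sigma_b;
};

static Hyper hyper_from_list(const List& h) {
  Hyper hy;
  hy.a = h["a"]; hy.b = h["b"];
  hy.c1 = h["c1"]; hy.d1 = h["d1"];
  hy.c2 = h["c2"]; hy.d2 = h["d2"];
  hy.r1 = h["r1"]; hy.u1 = h["u1"];
  hy.r2 = h["r2"]; hy.u2 = h["u2"];
  hy.alpha0 = h["alpha0"]; hy.gamma0 = h["gamma0"];
  hy.xi2sq = h["xi2sq"];
  hy.sigma_a = h["sigma_a"]; hy.sigma_b = h["sigma_b"];
  return hy;
}

struct State {
  arma::vec alpha, gamma, eta, v, s2;
  double beta, s1, tau, phi1sq, phi2sq, pi1, pi2, sigma2;
  int ind_beta;
  arma::ivec ind_eta;
};

// Conjugate normal moments for one coefficient given the current residual r
// (which still CONTAINS the coefficient's own contribution coef * z):
// partial residual pr = r + coef * z, so
//   sum w pr z = sum w r z + coef * sum w z^2.
// After drawing, the caller updates r += (coef_old - coef_new) * z.
static inline void coef_moments(const double* r, const double* z,
                                const double* w, int n, double coef,
                                double prior_var, double& mean, double& var) {
  double swzz = 0.0, swrz = 0.0;
  for (int i = 0; i < n; ++i) {
    double wz = w[i] * z[i];
    swzz += wz * z[i];
    swrz += wz * r[i];
  }
  var = 1.0 / (swzz + 1.0 / prior_var);
  mean = var * (swrz + coef * swzz);
}

static inline void shift_residual(double* r, const double* z, int n,
                                  double delta) {
  if (delta == 0.0) return;
  for (int i = 0; i < n; ++i) r[i] += delta * z[i];
}

// One full systematic scan. Order: alpha's, gamma's, beta, eta's, s1, s2k's,
// phi1^2, phi2^2, pi1, pi2, tau (or sigma^2), latent v.
// robust: LAD likelihood via exponential-scale-mixture latents v.
// pi_fixed: when true, pi1/pi2 are held at their current values (plain
// Laplace-prior variants use this with pi = 0).
// r is the running full-model residual, maintained incrementally; w is a
// scratch buffer for the precision weights.
static void sweep_impl(State& st, const arma::vec& y, const arma::mat& E,
                       const arma::mat& C, const arma::vec& x, const arma::mat& W,
                       const Hyper& hy, bool robust, bool pi_fixed,
                       arma::vec& r, arma::vec& w) {
  const int n = y.n_elem, q = E.n_cols, m = C.n_cols;
  double* rp = r.memptr();
  double* wp = w.memptr();

  if (robust) {
    if (st.tau <= 0.0 || arma::any(st.v <= 0.0))
      stop("invalid chain state: tau and v must be strictly positive");
    const double* vp = st.v.memptr();
    for (int i = 0; i < n; ++i) wp[i] = st.tau / (hy.xi2sq * vp[i]);
  } else {
    if (st.sigma2 <= 0.0) stop("invalid chain state: sigma2 must be positive");
    double wi = 1.0 / st.sigma2;
    for (int i = 0; i < n; ++i) wp[i] = wi;
  }

  double mean, var;
  for (int k = 0; k < q; ++k) {
    const double* z = E.colptr(k);
    coef_moments(rp, z, wp, n, st.alpha(k), hy.alpha0, mean, var);
    double nw = mean + std::sqrt(var) * norm_rand();
    shift_residual(rp, z, n, st.alpha(k) - nw);
    st.alpha(k) = nw;
  }
  for (int t = 0; t < m; ++t) {
    const double* z = C.colptr(t);
    coef_moments(rp, z, wp, n, st.gamma(t), hy.gamma0, mean, var);
    double nw = mean + std::sqrt(var) * norm_rand();
    shift_residual(rp, z, n, st.gamma(t) - nw);
    st.gamma(t) = nw;
  }
  {
    const double* z = x.memptr();
    coef_moments(rp, z, wp, n, st.beta, st.s1, mean, var);
    double l = spike_prob(mean, var, st.s1, st.pi1);
    double nw = spike_slab_draw(mean, var, l, st.ind_beta);
    shift_residual(rp, z, n, st.beta - nw);
    st.beta = nw;
  }
  for (int k = 0; k < q; ++k) {
    const double* z = W.colptr(k);
    coef_moments(rp, z, wp, n, st.eta(k), st.s2(k), mean, var);
    double l = spike_prob(mean, var, st.s2(k), st.pi2);
    int ind;
    double nw = spike_slab_draw(mean, var, l, ind);
    shift_residual(rp, z, n, st.eta(k) - nw);
    st.eta(k) = nw;
    st.ind_eta(k) = ind;
  }

  st.s1 = slab_variance_draw(st.beta, st.phi1sq);
  for (int k = 0; k < q; ++k) st.s2(k) = slab_variance_draw(st.eta(k), st.phi2sq);

  st.phi1sq = R::rgamma(hy.c1 + 1.0, 1.0 / (st.s1 / 2.0 + hy.d1));
  st.phi2sq = R::rgamma(hy.c2 + q, 1.0 / (arma::accu(st.s2) / 2.0 + hy.d2));

  if (!pi_fixed) {
    st.pi1 = R::rbeta(hy.r1 + 1.0 - st.ind_beta, hy.u1 + st.ind_beta);
    int k2 = arma::accu(st.ind_eta);
    st.pi2 = R::rbeta(hy.r2 + q - k2, hy.u2 + k2);
  }

  if (robust) {
    double* vp = st.v.memptr();
    double rate = hy.b;
    for (int i = 0; i < n; ++i)
      rate += rp[i] * rp[i] / (2.0 * hy.xi2sq * vp[i]) + vp[i];
    st.tau = R::rgamma(hy.a + 1.5 * n, 1.0 / rate);
    double two_tau = 2.0 * st.tau;
    for (int i = 0; i < n; ++i) {
      double r2 = std::max(rp[i] * rp[i], RESID2_FLOOR);
      double mu = std::sqrt(2.0 * hy.xi2sq / r2);
      vp[i] = 1.0 / rinvgauss1(mu, two_tau);
    }
  } else {
    double rate = hy.sigma_b + 0.5 * arma::dot(r, r);
    st.sigma2 = 1.0 / R::rgamma(hy.sigma_a + 0.5 * n, 1.0 / rate);
  }
}

static arma::vec full_residual(const State& st, const arma::vec& y,
                               const arma::mat& E, const arma::mat& C,
                               const arma::vec& x, const arma::mat& W) {
  arma::vec r = y - E * st.alpha - x * st.beta - W * st.eta;
  if (C.n_cols > 0) r -= C * st.gamma;
  return r;
}

static State state_from_list(const List& s, int q, int m) {
  State st;
  st.alpha = as<arma::vec>(s["alpha"]);
  st.gamma = (m > 0) ? as<arma::vec>(s["gamma"]) : arma::vec();
  st.beta = s["beta"];
  st.eta = as<arma::vec>(s["eta"]);
  st.v = as<arma::vec>(s["v"]);
  st.s1 = s["s1"];
  st.s2 = as<arma::vec>(s["s2"]);
  st.tau = s["tau"];
  st.phi1sq = s["phi1sq"];
  st.phi2sq = s["phi2sq"];
  st.pi1 = s["pi1"];
  st.pi2 = s["pi2"];
  st.sigma2 = s["sigma2"];
  st.ind_beta = (st.beta != 0.0) ? 1 : 0;
  st.ind_eta.set_size(q);
  for (int k = 0; k < q; ++k) st.ind_eta(k) = (st.eta(k) != 0.0) ? 1 : 0;
  return st;
}

static List state_to_list(const State& st) {
  return List::create(
    _["alpha"] = st.alpha, _["gamma"] = st.gamma, _["beta"] = st.beta,
    _["eta"] = st.eta, _["v"] = st.v, _["s1"] = st.s1, _["s2"] = st.s2,
    _["tau"] = st.tau, _["phi1sq"] = st.phi1sq, _["phi2sq"] = st.phi2sq,
    _["pi1"] = st.pi1, _["pi2"] = st.pi2, _["sigma2"] = st.sigma2,
    _["ind_beta"] = st.ind_beta, _["ind_eta"] = st.ind_eta);
}

// [[Rcpp::export]]
NumericVector cpp_weights(NumericVector v, double tau, double xi2sq) {
  int n = v.size();
  NumericVector w(n);
  if (tau <= 0.0) stop("invalid chain state: tau must be positive");
  for (int i = 0; i < n; ++i) {
    if (v[i] <= 0.0) stop("invalid chain state: v must be strictly positive");
    w[i] = tau / (xi2sq * v[i]);
  }
  return w;
}

// [[Rcpp::export]]
List cpp_normal_coef_update(arma::vec partial_residual, arma::vec predictor,
                            arma::vec w, double prior_var) {
  if (prior_var <= 0.0) stop("prior_var must be positive");
  double mean, var;
  // partial residual already excludes the coefficient, so coef = 0 here
  coef_moments(partial_residual.memptr(), predictor.memptr(), w.memptr(),
               partial_residual.n_elem, 0.0, prior_var, mean, var);
  double draw = mean + std::sqrt(var) * norm_rand();
  return List::create(_["mean"] = mean, _["variance"] = var, _["draw"] = draw);
}

// [[Rcpp::export]]
List cpp_spike_slab_update(arma::vec partial_residual, arma::vec predictor,
                           arma::vec w, double slab_var, double pi_spike) {
  if (slab_var <= 0.0) stop("slab_var must be positive");
  if (pi_spike < 0.0 || pi_spike > 1.0) stop("pi_spike must lie in [0, 1]");
  double mean, var;
  coef_moments(partial_residual.memptr(), predictor.memptr(), w.memptr(),
               partial_residual.n_elem, 0.0, slab_var, mean, var);
  double l = spike_prob(mean, var, slab_var, pi_spike);
  int ind;
  double value = spike_slab_draw(mean, var, l, ind);
  return List::create(_["spike_prob"] = l, _["mean"] = mean, _["variance"] = var,
                      _["value"] = value, _["indicator"] = ind);
}

// [[Rcpp::export]]
double cpp_update_slab_variance(double coef, double phisq) {
  if (phisq <= 0.0) stop("phisq must be positive");
  return slab_variance_draw(coef, phisq);
}

// [[Rcpp::export]]
NumericVector cpp_rinvgauss(int n, double mu, double lambda) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rinvgauss1(mu, lambda);
  return out;
}

// [[Rcpp::export]]
double cpp_update_tau(arma::vec residuals, arma::vec v, double a, double b,
                      double xi2sq) {
  if (arma::any(v <= 0.0)) stop("v must be strictly positive");
  int n = residuals.n_elem;
  double rate = b;
  for (int i = 0; i < n; ++i)
    rate += residuals(i) * residuals(i) / (2.0 * xi2sq * v(i)) + v(i);
  return R::rgamma(a + 1.5 * n, 1.0 / rate);
}

// [[Rcpp::export]]
NumericVector cpp_update_latent_v(arma::vec residuals, double tau, double xi2sq) {
  if (tau <= 0.0) stop("tau must be positive");
  int n = residuals.n_elem;
  NumericVector v(n);
  for (int i = 0; i < n; ++i) {
    double r2 = std::max(residuals(i) * residuals(i), RESID2_FLOOR);
    double mu = std::sqrt(2.0 * xi2sq / r2);
    v[i] = 1.0 / rinvgauss1(mu, 2.0 * tau);
  }
  return v;
}

// [[Rcpp::export]]
List cpp_gibbs_sweep(List state, arma::vec y, arma::mat E, arma::mat C,
                     arma::vec x, arma::mat W, List hyper, bool robust,
                     bool pi_fixed) {
  Hyper hy = hyper_from_list(hyper);
  State st = state_from_list(state, E.n_cols, C.n_cols);
  arma::vec r = full_residual(st, y, E, C, x, W);
  arma::vec w(y.n_elem);
  sweep_impl(st, y, E, C, x, W, hy, robust, pi_fixed, r, w);
  return state_to_list(st);
}

// [[Rcpp::export]]
List cpp_run_chain(arma::vec y, arma::mat E, arma::mat C, arma::vec x,
                   arma::mat W, List hyper, bool robust, bool sparse,
                   int iterations, int burn_in, List init,
                   NumericVector fix_pi) {
  if (iterations <= burn_in)
    stop("iterations must exceed burn_in");
  const int q = E.n_cols, m = C.n_cols;
  Hyper hy = hyper_from_list(hyper);
  State st = state_from_list(init, q, m);

  bool pi_fixed;
  if (!sparse) {
    st.pi1 = 0.0; st.pi2 = 0.0;
    pi_fixed = true;
  } else if (fix_pi.size() == 2) {
    st.pi1 = fix_pi[0]; st.pi2 = fix_pi[1];
    pi_fixed = true;
  } else {
    pi_fixed = false;
  }

  const int H = iterations - burn_in;
  arma::mat alpha_d(H, q), eta_d(H, q), s2_d(H, q);
  arma::mat gamma_d(H, std::max(m, 0));
  arma::vec beta_d(H), s1_d(H), tau_d(H), phi1_d(H), phi2_d(H), pi1_d(H),
      pi2_d(H), sigma2_d(H);
  arma::imat ind_eta_d(H, q);
  arma::ivec ind_beta_d(H);

  arma::vec r = full_residual(st, y, E, C, x, W);
  arma::vec w(y.n_elem);
  for (int it = 0; it < iterations; ++it) {
    // periodic full refresh guards against drift in the incremental residual
    if (it % 1000 == 0 && it > 0) r = full_residual(st, y, E, C, x, W);
    sweep_impl(st, y, E, C, x, W, hy, robust, pi_fixed, r, w);
    if (it >= burn_in) {
      int h = it - burn_in;
      alpha_d.row(h) = st.alpha.t();
      if (m > 0) gamma_d.row(h) = st.gamma.t();
      beta_d(h) = st.beta;
      eta_d.row(h) = st.eta.t();
      s1_d(h) = st.s1;
      s2_d.row(h) = st.s2.t();
      tau_d(h) = st.tau;
      phi1_d(h) = st.phi1sq;
      phi2_d(h) = st.phi2sq;
      pi1_d(h) = st.pi1;
      pi2_d(h) = st.pi2;
      sigma2_d(h) = st.sigma2;
      ind_beta_d(h) = st.ind_beta;
      ind_eta_d.row(h) = st.ind_eta.t();
    }
  }

  return List::create(
    _["alpha"] = alpha_d, _["gamma"] = gamma_d, _["beta"] = beta_d,
    _["eta"] = eta_d, _["s1"] = s1_d, _["s2"] = s2_d, _["tau"] = tau_d,
    _["phi1sq"] = phi1_d, _["phi2sq"] = phi2_d, _["pi1"] = pi1_d,
    _["pi2"] = pi2_d, _["sigma2"] = sigma2_d, _["ind_beta"] = ind_beta_d,
    _["ind_eta"] = ind_eta_d);
}
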