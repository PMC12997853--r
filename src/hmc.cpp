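// Log posterior (with analytic gradient) for the Bayesian M-spline hazard
// model, and an adaptive Hamiltonian Monte Carlo sampler.
//
// Model: h(t|x) = eta0 exp(beta'x_ph) sum_i p_i(x) b_i(t), with simplex
// weights p(x) = softmax(gamma(x)), gamma_1 = 0,
// gamma_i(x) = mu_i + sigma * eps_i + delta_i' x_np (centred
// parameterisation: eps are the sampled coordinates; the joint density is
// bounded there, which a gamma-space parameterisation would not be as
// sigma -> 0). Priors: log eta ~ N, eps ~ weighted logistic random walk
// (or exchangeable Logistic(0,1)), sigma ~ Gamma (shape, rate), beta ~ N,
// delta_is ~ N(0, tau_s), tau_s ~ Gamma; all evaluated on the unconstrained
// scale (log eta, eps, log sigma, beta, delta, log tau) with Jacobians.
//
// Parameter vector layout:
//   [0]               log_eta
//   [1 .. nb-1]       eps_2 .. eps_nb
//   [nb]              log_sigma
//   [nb+1 .. nb+P]    beta
//   next (nb-1)*Q     delta (stacked per non-PH covariate, rows i = 2..nb)
//   last Q            log_tau

#include <Rcpp.h>
using namespace Rcpp;

struct ModelData {
  NumericMatrix B_ev;    // n_ev x nb, basis at event times
  NumericMatrix I_all;   // n x nb, integrated basis at all times
  NumericMatrix Xph_ev, Xph_all;  // PH covariates (may have 0 cols)
  NumericMatrix Xnp_ev, Xnp_all;  // non-PH covariates (may have 0 cols)
  NumericVector mu;      // nb, multinomial-logit prior means
  NumericVector w;       // nb-1, random-walk weights
  int coef_model;        // 0 = random walk, 1 = exchangeable
  double eta_mean, eta_sd, sigma_shape, sigma_rate;
  NumericVector beta_mean, beta_sd;
  double tau_shape, tau_rate;
};

static ModelData unpack(const List& d) {
  ModelData m;
  m.B_ev = as<NumericMatrix>(d["B_ev"]);
  m.I_all = as<NumericMatrix>(d["I_all"]);
  m.Xph_ev = as<NumericMatrix>(d["Xph_ev"]);
  m.Xph_all = as<NumericMatrix>(d["Xph_all"]);
  m.Xnp_ev = as<NumericMatrix>(d["Xnp_ev"]);
  m.Xnp_all = as<NumericMatrix>(d["Xnp_all"]);
  m.mu = as<NumericVector>(d["mu"]);
  m.w = as<NumericVector>(d["w"]);
  m.coef_model = as<int>(d["coef_model"]);
  m.eta_mean = as<double>(d["eta_mean"]);
  m.eta_sd = as<double>(d["eta_sd"]);
  m.sigma_shape = as<double>(d["sigma_shape"]);
  m.sigma_rate = as<double>(d["sigma_rate"]);
  m.beta_mean = as<NumericVector>(d["beta_mean"]);
  m.beta_sd = as<NumericVector>(d["beta_sd"]);
  m.tau_shape = as<double>(d["tau_shape"]);
  m.tau_rate = as<double>(d["tau_rate"]);
  return m;
}

// log posterior and gradient; returns log posterior, fills grad
static double logpost_grad(const ModelData& m, const NumericVector& theta,
                           std::vector<double>& grad) {
  const int nb = m.mu.size();
  const int P = m.Xph_all.ncol();
  const int Q = m.Xnp_all.ncol();
  const int n = m.I_all.nrow();
  const int n_ev = m.B_ev.nrow();
  const int npar = 1 + (nb - 1) + 1 + P + (nb - 1) * Q + Q;
  grad.assign(npar, 0.0);

  const double log_eta = theta[0];
  const double eta = std::exp(log_eta);
  const double log_sigma = theta[nb];
  const double sigma = std::exp(log_sigma);
  std::vector<double> eps(nb, 0.0);
  for (int i = 1; i < nb; ++i) eps[i] = theta[i];
  std::vector<double> beta(P);
  for (int p = 0; p < P; ++p) beta[p] = theta[nb + 1 + p];
  const int off_d = nb + 1 + P;
  const int off_t = off_d + (nb - 1) * Q;
  std::vector<double> tau(Q);
  for (int q = 0; q < Q; ++q) tau[q] = std::exp(theta[off_t + q]);

  // delta full matrix (nb x Q), row 0 fixed at 0
  std::vector<double> delta(nb * Q, 0.0);
  for (int q = 0; q < Q; ++q)
    for (int i = 1; i < nb; ++i)
      delta[i + q * nb] = theta[off_d + q * (nb - 1) + (i - 1)];

  double ll = 0.0;
  std::vector<double> g(nb), pr(nb), dgam(nb);
  std::vector<double> dgam_tot(nb, 0.0);            // for eps / sigma chain
  std::vector<double> ddelta(nb * Q, 0.0);          // likelihood grad wrt delta

  // one pass over a set of subjects; which = 0 -> cumulative hazard terms
  // (all subjects, I_all), which = 1 -> event terms (B_ev)
  for (int which = 0; which < 2; ++which) {
    const NumericMatrix& Bm = (which == 0) ? m.I_all : m.B_ev;
    const NumericMatrix& Xph = (which == 0) ? m.Xph_all : m.Xph_ev;
    const NumericMatrix& Xnp = (which == 0) ? m.Xnp_all : m.Xnp_ev;
    const int nrow = (which == 0) ? n : n_ev;
    for (int j = 0; j < nrow; ++j) {
      double gmax = 0.0;
      for (int i = 0; i < nb; ++i) {
        double gi = m.mu[i] + sigma * eps[i];
        for (int q = 0; q < Q; ++q) gi += delta[i + q * nb] * Xnp(j, q);
        g[i] = gi;
        if (gi > gmax) gmax = gi;
      }
      double sum = 0.0;
      for (int i = 0; i < nb; ++i) { pr[i] = std::exp(g[i] - gmax); sum += pr[i]; }
      for (int i = 0; i < nb; ++i) pr[i] /= sum;
      double lin = log_eta;
      for (int p = 0; p < P; ++p) lin += beta[p] * Xph(j, p);
      const double scale = std::exp(lin);
      double v = 0.0;
      for (int i = 0; i < nb; ++i) v += pr[i] * Bm(j, i);
      if (which == 0) {                      // - H(t_j | x_j)
        ll -= scale * v;
        grad[0] -= scale * v;
        for (int p = 0; p < P; ++p) grad[nb + 1 + p] -= scale * v * Xph(j, p);
        for (int i = 0; i < nb; ++i) {
          const double d = -scale * pr[i] * (Bm(j, i) - v);
          dgam[i] = d;
        }
      } else {                               // + log h(t_j | x_j)
        if (v <= 0.0 || !R_finite(v)) return R_NegInf;
        ll += lin + std::log(v);
        grad[0] += 1.0;
        for (int p = 0; p < P; ++p) grad[nb + 1 + p] += Xph(j, p);
        for (int i = 0; i < nb; ++i)
          dgam[i] = pr[i] * (Bm(j, i) - v) / v;
      }
      for (int i = 0; i < nb; ++i) dgam_tot[i] += dgam[i];
      for (int q = 0; q < Q; ++q) {
        const double x = Xnp(j, q);
        if (x != 0.0)
          for (int i = 1; i < nb; ++i) ddelta[i + q * nb] += dgam[i] * x;
      }
    }
  }

  // chain rule: gamma_i = mu_i + sigma * eps_i + delta' x
  for (int i = 1; i < nb; ++i) {
    grad[i] += sigma * dgam_tot[i];
    grad[nb] += sigma * eps[i] * dgam_tot[i];
  }
  for (int q = 0; q < Q; ++q)
    for (int i = 1; i < nb; ++i)
      grad[off_d + q * (nb - 1) + (i - 1)] += ddelta[i + q * nb];

  double lp = ll;

  // log eta ~ N(eta_mean, eta_sd)
  {
    const double z = (log_eta - m.eta_mean) / m.eta_sd;
    lp += -0.5 * z * z - std::log(m.eta_sd) - M_LN_SQRT_2PI;
    grad[0] += -z / m.eta_sd;
  }
  // eps prior
  if (m.coef_model == 0) {                   // weighted random walk
    for (int i = 1; i < nb; ++i) {
      const double wi = m.w[i - 1];
      const double z = (eps[i] - eps[i - 1]) / wi;
      lp += -z - 2.0 * std::log1p(std::exp(-z)) - std::log(wi);
      const double dz = -std::tanh(z / 2.0);   // d logpdf / dz
      grad[i] += dz / wi;
      if (i - 1 >= 1) grad[i - 1] -= dz / wi;
    }
  } else {                                   // exchangeable Logistic(0, 1)
    for (int i = 1; i < nb; ++i) {
      const double z = eps[i];
      lp += -z - 2.0 * std::log1p(std::exp(-z));
      grad[i] += -std::tanh(z / 2.0);
    }
  }
  // sigma ~ Gamma(shape, rate), with log-Jacobian
  lp += m.sigma_shape * log_sigma - m.sigma_rate * sigma +
    m.sigma_shape * std::log(m.sigma_rate) - R::lgammafn(m.sigma_shape);
  grad[nb] += m.sigma_shape - m.sigma_rate * sigma;
  // beta ~ N
  for (int p = 0; p < P; ++p) {
    const double z = (beta[p] - m.beta_mean[p]) / m.beta_sd[p];
    lp += -0.5 * z * z - std::log(m.beta_sd[p]) - M_LN_SQRT_2PI;
    grad[nb + 1 + p] += -z / m.beta_sd[p];
  }
  // delta_is ~ N(0, tau_s); tau_s ~ Gamma, with log-Jacobian
  for (int q = 0; q < Q; ++q) {
    const double tq = tau[q];
    double s2 = 0.0;
    for (int i = 1; i < nb; ++i) {
      const double d = delta[i + q * nb];
      s2 += d * d;
      grad[off_d + q * (nb - 1) + (i - 1)] += -d / (tq * tq);
    }
    lp += -0.5 * s2 / (tq * tq) - (nb - 1) * (std::log(tq) + M_LN_SQRT_2PI);
    grad[off_t + q] += s2 / (tq * tq) - (nb - 1);
    lp += m.tau_shape * theta[off_t + q] - m.tau_rate * tq +
      m.tau_shape * std::log(m.tau_rate) - R::lgammafn(m.tau_shape);
    grad[off_t + q] += m.tau_shape - m.tau_rate * tq;
  }
  return lp;
}

// [[Rcpp::export]]
List mspline_logpost_grad(List data, NumericVector theta) {
  ModelData m = unpack(data);
  std::vector<double> grad;
  double lp = logpost_grad(m, theta, grad);
  return List::create(_["lp"] = lp, _["grad"] = NumericVector(grad.begin(), grad.end()));
}

// ---- HMC ----

struct State {
  NumericVector theta;
  std::vector<double> grad;
  double lp;
};

static bool leapfrog(const ModelData& m, State& s, std::vector<double>& r,
                     const std::vector<double>& inv_mass, double step, int L,
                     double H0, bool& divergent) {
  const int npar = s.theta.size();
  divergent = false;
  for (int l = 0; l < L; ++l) {
    for (int k = 0; k < npar; ++k) r[k] += 0.5 * step * s.grad[k];
    for (int k = 0; k < npar; ++k) s.theta[k] += step * inv_mass[k] * r[k];
    s.lp = logpost_grad(m, s.theta, s.grad);
    if (!R_finite(s.lp)) { divergent = true; return false; }
    for (int k = 0; k < npar; ++k) r[k] += 0.5 * step * s.grad[k];
    double kin = 0.0;
    for (int k = 0; k < npar; ++k) kin += 0.5 * inv_mass[k] * r[k] * r[k];
    if ((-s.lp + kin) - H0 > 1000.0) { divergent = true; return false; }
  }
  return true;
}

// One adaptive HMC chain. Warmup adapts a dual-averaged step size in two
// phases with a diagonal mass matrix estimated between them; sampling uses
// the fixed adapted settings with a jittered number of leapfrog steps.
// Uses R's RNG, so set.seed() in R makes chains reproducible.
// [[Rcpp::export]]
List hmc_chain(List data, NumericVector init, int n_warmup, int n_sample,
               double target_accept = 0.8, int max_steps = 48,
               double sim_length = 1.0) {
  ModelData m = unpack(data);
  const int npar = init.size();
  State s;
  s.theta = clone(init);
  s.lp = logpost_grad(m, s.theta, s.grad);
  if (!R_finite(s.lp)) stop("initial values have non-finite log posterior");

  std::vector<double> inv_mass(npar, 1.0);
  // crude initial step size: scale until acceptance crosses 0.5
  double step = 0.1;
  {
    std::vector<double> r(npar);
    for (int k = 0; k < npar; ++k) r[k] = norm_rand();
    double H0 = -s.lp;
    for (int k = 0; k < npar; ++k) H0 += 0.5 * r[k] * r[k];
    State t; t.theta = clone(s.theta); t.grad = s.grad; t.lp = s.lp;
    bool div;
    std::vector<double> r2 = r;
    leapfrog(m, t, r2, inv_mass, step, 1, H0, div);
    double H1 = div ? R_PosInf : -t.lp;
    if (!div) for (int k = 0; k < npar; ++k) H1 += 0.5 * r2[k] * r2[k];
    double a = std::exp(H0 - H1);
    int dir = (a > 0.5) ? 1 : -1;
    for (int it = 0; it < 50; ++it) {
      step *= (dir == 1) ? 2.0 : 0.5;
      State u; u.theta = clone(s.theta); u.grad = s.grad; u.lp = s.lp;
      std::vector<double> r3 = r;
      leapfrog(m, u, r3, inv_mass, step, 1, H0, div);
      double H = div ? R_PosInf : -u.lp;
      if (!div) for (int k = 0; k < npar; ++k) H += 0.5 * r3[k] * r3[k];
      double ap = std::exp(H0 - H);
      if ((dir == 1 && ap < 0.5) || (dir == -1 && ap > 0.5)) break;
    }
  }

  // dual averaging state
  double mu_da = std::log(10.0 * step), log_step = std::log(step);
  double log_step_bar = 0.0, Hbar = 0.0;
  const double gamma_da = 0.05, t0 = 10.0, kappa = 0.75;
  int da_iter = 0;
  auto da_reset = [&](double cur) {
    mu_da = std::log(10.0 * cur); log_step = std::log(cur);
    log_step_bar = 0.0; Hbar = 0.0; da_iter = 0;
  };

  const int phase1 = n_warmup / 2;
  NumericMatrix win(phase1 - phase1 / 2, npar);   // second half of phase 1
  int win_i = 0;

  NumericMatrix draws(n_sample, npar);
  int n_div = 0;
  double acc_sum = 0.0;

  for (int iter = 0; iter < n_warmup + n_sample; ++iter) {
    const bool warm = iter < n_warmup;
    const double cur_step = warm ? std::exp(log_step) : std::exp(log_step_bar);
    int Lmax = (int)std::ceil(sim_length / cur_step);
    if (Lmax < 1) Lmax = 1;
    if (Lmax > max_steps) Lmax = max_steps;
    int L = 1 + (int)std::floor(unif_rand() * Lmax);
    if (L > Lmax) L = Lmax;

    std::vector<double> r(npar);
    for (int k = 0; k < npar; ++k) r[k] = norm_rand() / std::sqrt(inv_mass[k]);
    double H0 = -s.lp;
    for (int k = 0; k < npar; ++k) H0 += 0.5 * inv_mass[k] * r[k] * r[k];

    State prop; prop.theta = clone(s.theta); prop.grad = s.grad; prop.lp = s.lp;
    bool div = false;
    bool ok = leapfrog(m, prop, r, inv_mass, cur_step, L, H0, div);
    double accept = 0.0;
    if (ok) {
      double H1 = -prop.lp;
      for (int k = 0; k < npar; ++k) H1 += 0.5 * inv_mass[k] * r[k] * r[k];
      accept = std::exp(std::min(0.0, H0 - H1));
      if (unif_rand() < accept) s = prop;
    }
    if (div && !warm) ++n_div;

    if (warm) {
      ++da_iter;
      Hbar = (1.0 - 1.0 / (da_iter + t0)) * Hbar +
             (target_accept - accept) / (da_iter + t0);
      log_step = mu_da - std::sqrt((double)da_iter) / gamma_da * Hbar;
      const double eta_w = std::pow((double)da_iter, -kappa);
      log_step_bar = eta_w * log_step + (1.0 - eta_w) * log_step_bar;
      if (iter >= phase1 / 2 && iter < phase1 && win_i < win.nrow()) {
        for (int k = 0; k < npar; ++k) win(win_i, k) = s.theta[k];
        ++win_i;
      }
      if (iter == phase1 - 1 && win_i > 10) {
        for (int k = 0; k < npar; ++k) {
          double mean = 0.0;
          for (int j = 0; j < win_i; ++j) mean += win(j, k);
          mean /= win_i;
          double v = 0.0;
          for (int j = 0; j < win_i; ++j)
            v += (win(j, k) - mean) * (win(j, k) - mean);
          v /= (win_i - 1);
          inv_mass[k] = v + 1e-4;   // inverse mass = posterior variance
        }
        da_reset(std::exp(log_step_bar));
      }
    } else {
      acc_sum += accept;
      for (int k = 0; k < npar; ++k) draws(iter - n_warmup, k) = s.theta[k];
    }
  }

  return List::create(_["draws"] = draws,
                      _["divergences"] = n_div,
                      _["accept_rate"] = acc_sum / n_sample,
                      _["step_size"] = std::exp(log_step_bar),
                      _["inv_mass"] = NumericVector(inv_mass.begin(), inv_mass.end()));
}
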