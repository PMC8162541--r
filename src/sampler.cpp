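#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "wfpt.h"

using namespace Rcpp;

// One MCMC chain for the per-occasion hierarchical diffusion model.
//
// Person p has free parameters: drift intercept nu_p, boundary intercept
// a_p, correct non-decision time tp_p, error non-decision time tm_p, and
// effect-coded condition deviations nueff_{p,c}, aeff_{p,c} for the first
// nine conditions (the tenth is minus their sum).  Person parameters are
// exchangeable draws from group-level normal distributions; group effect
// means are themselves effect-coded (nine free, tenth = -sum).  Starting
// point is fixed at w = 0.5 and inter-trial variabilities at zero.
//
// Updates: adaptive random-walk Metropolis for everything with a trial
// likelihood; conjugate (truncated) normal Gibbs draws for group means;
// random-walk Metropolis on log scale for group spreads (half-normal
// priors).  Proposal scales adapt only during burn-in.  All randomness
// comes from R's RNG, so a chain is reproducible under set.seed().

static const double EPS_DENS = 1e-7;

struct Model {
  int n, N;
  std::vector<double> rt;
  std::vector<int> correct, cond, person;
  std::vector<std::vector<int> > idx_all, idx_corr, idx_err;
  std::vector<std::vector<std::vector<int> > > idx_pc;
  // trials of condition c plus the tenth condition, per person (the
  // tenth effect is minus the sum, so it moves with every effect)
  std::vector<std::vector<std::vector<int> > > idx_pc_pair;
};

struct State {
  std::vector<double> nu, a, tp, tm;
  std::vector<std::vector<double> > nueff, aeff; // N x 9
  double mu_nu, sig_nu, mu_a, sig_a, mu_tp, sig_tp, mu_tm, sig_tm;
  std::vector<double> delta_nu, delta_a;          // 9
  double sig_ne, sig_ae;
};

static inline double eff_of(const std::vector<double>& e, int c) {
  if (c < 9) return e[c];
  double s = 0.0;
  for (int k = 0; k < 9; ++k) s += e[k];
  return -s;
}

static inline double trial_ll(const Model& M, const State& S, int i) {
  int p = M.person[i], c = M.cond[i];
  double v = S.nu[p] + eff_of(S.nueff[p], c);
  double A = S.a[p] + eff_of(S.aeff[p], c);
  if (A <= 0.0) return R_NegInf;
  double tau = M.correct[i] ? S.tp[p] : S.tm[p];
  double td = M.rt[i] - tau;
  if (td <= 0.0) return R_NegInf;
  // upper (correct) boundary density via reflection; w = 0.5
  double drift = M.correct[i] ? -v : v;
  return wfpt_logpdf1(td, drift, A, 0.5, EPS_DENS);
}

static inline double sum_ll(const std::vector<double>& cur,
                            const std::vector<int>& idx) {
  double s = 0.0;
  for (size_t k = 0; k < idx.size(); ++k) s += cur[idx[k]];
  return s;
}

// propose/accept for a scalar person parameter; returns 1 on accept
static std::vector<double> g_scratch;

static int mh_update(const Model& M, State& S, std::vector<double>& cur,
                     double& par, double scale,
                     double prior_mu, double prior_sd,
                     const std::vector<int>& idx, bool positive) {
  double old = par;
  double prop = old + scale * norm_rand();
  if (positive && prop < 0.0) return 0;
  double dprior = R::dnorm(prop, prior_mu, prior_sd, 1) -
                  R::dnorm(old, prior_mu, prior_sd, 1);
  par = prop;
  double new_sum = 0.0;
  std::vector<double>& newll = g_scratch;
  if (newll.size() < idx.size()) newll.resize(idx.size());
  for (size_t k = 0; k < idx.size(); ++k) {
    newll[k] = trial_ll(M, S, idx[k]);
    if (newll[k] == R_NegInf) { par = old; return 0; }
    new_sum += newll[k];
  }
  double old_sum = sum_ll(cur, idx);
  double la = dprior + new_sum - old_sum;
  if (std::log(unif_rand()) < la) {
    for (size_t k = 0; k < idx.size(); ++k) cur[idx[k]] = newll[k];
    return 1;
  }
  par = old;
  return 0;
}

// joint adaptive update of (nu_p, a_p, tp_p): random-walk proposal from a
// per-person empirical covariance (learned during burn-in) times a scalar
// step size adapted to ~30% acceptance
struct Joint3 {
  double m[3];
  double C[9];
  double L[9];
  double lambda;
  long t;
  void init(double nu, double a, double tp) {
    m[0] = nu; m[1] = a; m[2] = tp;
    for (int i = 0; i < 9; ++i) C[i] = 0.0;
    C[0] = 0.02; C[4] = 0.02; C[8] = 2e-4;
    lambda = 1.0; t = 0;
    chol();
  }
  void chol() {
    // 3x3 Cholesky of C + jitter
    double A[9];
    for (int i = 0; i < 9; ++i) A[i] = C[i];
    A[0] += 1e-8; A[4] += 1e-8; A[8] += 1e-10;
    L[0] = std::sqrt(A[0]);
    L[3] = A[3] / L[0];
    L[6] = A[6] / L[0];
    L[4] = std::sqrt(std::max(A[4] - L[3] * L[3], 1e-12));
    L[7] = (A[7] - L[6] * L[3]) / L[4];
    L[8] = std::sqrt(std::max(A[8] - L[6] * L[6] - L[7] * L[7], 1e-14));
    L[1] = L[2] = L[5] = 0.0;
  }
  void learn(double nu, double a, double tp) {
    ++t;
    double x[3] = {nu, a, tp};
    for (int i = 0; i < 3; ++i) {
      double d = x[i] - m[i];
      m[i] += d / t;
    }
    if (t > 1) {
      double w = 1.0 / t;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double d = (x[i] - m[i]) * (x[j] - m[j]);
          C[3 * i + j] = (1.0 - w) * C[3 * i + j] + w * d * (double)t / (t - 1.0);
        }
    }
    if (t % 50 == 0) chol();
  }
};

static int mh_joint3(const Model& M, State& S, std::vector<double>& cur,
                     int p, Joint3& J) {
  double z[3] = {norm_rand(), norm_rand(), norm_rand()};
  double step[3];
  double sc = J.lambda * 2.38 / std::sqrt(3.0);
  step[0] = sc * J.L[0] * z[0];
  step[1] = sc * (J.L[3] * z[0] + J.L[4] * z[1]);
  step[2] = sc * (J.L[6] * z[0] + J.L[7] * z[1] + J.L[8] * z[2]);
  double old_nu = S.nu[p], old_a = S.a[p], old_tp = S.tp[p];
  double nu_n = old_nu + step[0], a_n = old_a + step[1],
         tp_n = old_tp + step[2];
  if (a_n <= 0.0 || tp_n < 0.0) return 0;
  double dprior = R::dnorm(nu_n, S.mu_nu, S.sig_nu, 1) -
                  R::dnorm(old_nu, S.mu_nu, S.sig_nu, 1) +
                  R::dnorm(a_n, S.mu_a, S.sig_a, 1) -
                  R::dnorm(old_a, S.mu_a, S.sig_a, 1) +
                  R::dnorm(tp_n, S.mu_tp, S.sig_tp, 1) -
                  R::dnorm(old_tp, S.mu_tp, S.sig_tp, 1);
  S.nu[p] = nu_n; S.a[p] = a_n; S.tp[p] = tp_n;
  const std::vector<int>& idx = M.idx_all[p];
  double new_sum = 0.0;
  std::vector<double>& newll = g_scratch;
  if (newll.size() < idx.size()) newll.resize(idx.size());
  for (size_t k = 0; k < idx.size(); ++k) {
    newll[k] = trial_ll(M, S, idx[k]);
    if (newll[k] == R_NegInf) {
      S.nu[p] = old_nu; S.a[p] = old_a; S.tp[p] = old_tp;
      return 0;
    }
    new_sum += newll[k];
  }
  double la = dprior + new_sum - sum_ll(cur, idx);
  if (std::log(unif_rand()) < la) {
    for (size_t k = 0; k < idx.size(); ++k) cur[idx[k]] = newll[k];
    return 1;
  }
  S.nu[p] = old_nu; S.a[p] = old_a; S.tp[p] = old_tp;
  return 0;
}

static inline double rtnorm_pos(double m, double s) {
  double plo = R::pnorm(0.0, m, s, 1, 0);
  double u = plo + unif_rand() * (1.0 - plo);
  if (u >= 1.0) u = 1.0 - 1e-12;
  return R::qnorm(u, m, s, 1, 0);
}

// conjugate normal draw for a group mean
static inline double gibbs_mean(const std::vector<double>& x, double sig,
                                double m0, double s0, bool positive) {
  double n = (double)x.size(), sx = 0.0;
  for (size_t i = 0; i < x.size(); ++i) sx += x[i];
  double prec = 1.0 / (s0 * s0) + n / (sig * sig);
  double m = (m0 / (s0 * s0) + sx / (sig * sig)) / prec;
  double s = std::sqrt(1.0 / prec);
  return positive ? rtnorm_pos(m, s) : m + s * norm_rand();
}

// MH on log sigma with half-normal(0, scale) prior; x are the deviates
// with means mu (recycled if length 1)
static int mh_sigma(double& sig, double prop_ls,
                    const std::vector<double>& x,
                    const std::vector<double>& mu, double hn_scale) {
  double old = sig;
  double prop = old * std::exp(prop_ls * norm_rand());
  double la = 0.0;
  // half-normal prior + log-scale Jacobian
  la += -(prop * prop - old * old) / (2.0 * hn_scale * hn_scale);
  la += std::log(prop) - std::log(old);
  double n = (double)x.size();
  la += -n * (std::log(prop) - std::log(old));
  double ss_new = 0.0, ss_old = 0.0;
  for (size_t i = 0; i < x.size(); ++i) {
    double m = (mu.size() == 1) ? mu[0] : mu[i];
    double d = x[i] - m;
    ss_new += d * d / (2.0 * prop * prop);
    ss_old += d * d / (2.0 * old * old);
  }
  la += ss_old - ss_new;
  if (std::log(unif_rand()) < la) { sig = prop; return 1; }
  return 0;
}

// [[Rcpp::export]]
List run_hier_ddm_chain_cpp(NumericVector rt, IntegerVector correct,
                        IntegerVector cond, IntegerVector person,
                        int n_person, List init, List priors,
                        int n_iter, int n_burnin) {
  Model M;
  M.n = rt.size();
  M.N = n_person;
  M.rt.assign(rt.begin(), rt.end());
  M.correct.assign(correct.begin(), correct.end());
  M.cond.assign(cond.begin(), cond.end());
  M.person.assign(person.begin(), person.end());
  M.idx_all.resize(M.N);
  M.idx_corr.resize(M.N);
  M.idx_err.resize(M.N);
  M.idx_pc.assign(M.N, std::vector<std::vector<int> >(10));
  for (int i = 0; i < M.n; ++i) {
    int p = M.person[i];
    M.idx_all[p].push_back(i);
    if (M.correct[i]) M.idx_corr[p].push_back(i);
    else M.idx_err[p].push_back(i);
    M.idx_pc[p][M.cond[i]].push_back(i);
  }
  M.idx_pc_pair.assign(M.N, std::vector<std::vector<int> >(9));
  for (int p = 0; p < M.N; ++p)
    for (int c = 0; c < 9; ++c) {
      M.idx_pc_pair[p][c] = M.idx_pc[p][c];
      M.idx_pc_pair[p][c].insert(M.idx_pc_pair[p][c].end(),
                                 M.idx_pc[p][9].begin(),
                                 M.idx_pc[p][9].end());
    }

  State S;
  {
    NumericVector nu0 = init["nu"], a0 = init["a"], tp0 = init["tau_plus"],
                  tm0 = init["tau_minus"];
    S.nu.assign(nu0.begin(), nu0.end());
    S.a.assign(a0.begin(), a0.end());
    S.tp.assign(tp0.begin(), tp0.end());
    S.tm.assign(tm0.begin(), tm0.end());
    S.nueff.assign(M.N, std::vector<double>(9, 0.0));
    S.aeff.assign(M.N, std::vector<double>(9, 0.0));
    S.mu_nu = as<double>(init["mu_nu"]);
    S.mu_a = as<double>(init["mu_a"]);
    S.mu_tp = as<double>(init["mu_tau_plus"]);
    S.mu_tm = as<double>(init["mu_tau_minus"]);
    S.sig_nu = 0.3; S.sig_a = 0.3; S.sig_tp = 0.05; S.sig_tm = 0.1;
    S.delta_nu.assign(9, 0.0);
    S.delta_a.assign(9, 0.0);
    S.sig_ne = 0.1; S.sig_ae = 0.05;
  }

  const double mu_nu_m = priors["mu_nu_mean"], mu_nu_s = priors["mu_nu_sd"];
  const double mu_a_m = priors["mu_a_mean"], mu_a_s = priors["mu_a_sd"];
  const double mu_tp_m = priors["mu_tau_mean"], mu_tp_s = priors["mu_tau_sd"];
  const double sig_nu_sc = priors["sigma_nu_scale"];
  const double sig_a_sc = priors["sigma_a_scale"];
  const double sig_t_sc = priors["sigma_tau_scale"];
  const double d_nu_sd = priors["delta_nu_sd"];
  const double d_a_sd = priors["delta_a_sd"];
  const double sig_ne_sc = priors["sigma_nu_eff_scale"];
  const double sig_ae_sc = priors["sigma_a_eff_scale"];

  // current per-trial log-likelihood cache
  std::vector<double> cur(M.n);
  for (int i = 0; i < M.n; ++i) {
    cur[i] = trial_ll(M, S, i);
    if (cur[i] == R_NegInf) {
      stop("non-finite log-density at initialization (trial %d, person %d)",
           i + 1, M.person[i] + 1);
    }
  }

  // proposal scales / joint proposal state
  std::vector<Joint3> J(M.N);
  for (int p = 0; p < M.N; ++p) J[p].init(S.nu[p], S.a[p], S.tp[p]);
  std::vector<double> s_tm(M.N, 0.05), s_ne(M.N, 0.15), s_ae(M.N, 0.12);
  double s_snu = 0.2, s_sa = 0.2, s_stp = 0.2, s_stm = 0.3, s_sne = 0.2,
         s_sae = 0.2;

  int n_keep = n_iter - n_burnin;
  int npar = 28 + 22 * M.N;
  NumericMatrix draws(n_keep, npar);

  std::vector<int> acc_joint(M.N, 0), acc_tm(M.N, 0), acc_ne(M.N, 0),
      acc_ae(M.N, 0);

  for (int it = 0; it < n_iter; ++it) {
    double gain = (it < n_burnin)
                      ? std::min(0.25, 3.0 / std::sqrt((double)it + 10.0))
                      : 0.0;
    for (int p = 0; p < M.N; ++p) {
      int acc;
      // two joint sweeps of (nu, a, tau_plus) per iteration
      for (int rep = 0; rep < 2; ++rep) {
        acc = mh_joint3(M, S, cur, p, J[p]);
        if (gain > 0) {
          J[p].lambda *= std::exp(gain * (acc - 0.30));
          J[p].learn(S.nu[p], S.a[p], S.tp[p]);
        }
        acc_joint[p] += acc;
      }
      // tau_minus: informed only by error trials (possibly none), so
      // its updates are cheap; sweep it three times per iteration
      for (int rep = 0; rep < 3; ++rep) {
        acc = mh_update(M, S, cur, S.tm[p], s_tm[p], S.mu_tm, S.sig_tm,
                        M.idx_err[p], true);
        if (gain > 0) s_tm[p] *= std::exp(gain * (acc - 0.44));
        acc_tm[p] += acc;
      }

      // condition deviations: proposing c also moves the tenth
      // condition. The drift and boundary families alternate across
      // iterations (each family's kernel leaves the target invariant,
      // so the two-iteration composition does too) to halve the cost
      // of these nuisance updates.
      int acc_sum = 0;
      if ((it + p) % 2 == 0) {
        for (int c = 0; c < 9; ++c) {
          acc_sum += mh_update(M, S, cur, S.nueff[p][c], s_ne[p],
                               S.delta_nu[c], S.sig_ne,
                               M.idx_pc_pair[p][c], false);
        }
        if (gain > 0) s_ne[p] *= std::exp(gain * (acc_sum / 9.0 - 0.44));
        acc_ne[p] += acc_sum;
      } else {
        for (int c = 0; c < 9; ++c) {
          acc_sum += mh_update(M, S, cur, S.aeff[p][c], s_ae[p],
                               S.delta_a[c], S.sig_ae,
                               M.idx_pc_pair[p][c], false);
        }
        if (gain > 0) s_ae[p] *= std::exp(gain * (acc_sum / 9.0 - 0.44));
        acc_ae[p] += acc_sum;
      }
    }

    // group-level updates
    S.mu_nu = gibbs_mean(S.nu, S.sig_nu, mu_nu_m, mu_nu_s, false);
    S.mu_a = gibbs_mean(S.a, S.sig_a, mu_a_m, mu_a_s, true);
    S.mu_tp = gibbs_mean(S.tp, S.sig_tp, mu_tp_m, mu_tp_s, true);
    S.mu_tm = gibbs_mean(S.tm, S.sig_tm, mu_tp_m, mu_tp_s, true);
    {
      std::vector<double> mu1(1);
      mu1[0] = S.mu_nu;
      int a1 = mh_sigma(S.sig_nu, s_snu, S.nu, mu1, sig_nu_sc);
      if (gain > 0) s_snu *= std::exp(gain * (a1 - 0.44));
      mu1[0] = S.mu_a;
      a1 = mh_sigma(S.sig_a, s_sa, S.a, mu1, sig_a_sc);
      if (gain > 0) s_sa *= std::exp(gain * (a1 - 0.44));
      mu1[0] = S.mu_tp;
      a1 = mh_sigma(S.sig_tp, s_stp, S.tp, mu1, sig_t_sc);
      if (gain > 0) s_stp *= std::exp(gain * (a1 - 0.44));
      mu1[0] = S.mu_tm;
      a1 = mh_sigma(S.sig_tm, s_stm, S.tm, mu1, sig_t_sc);
      if (gain > 0) s_stm *= std::exp(gain * (a1 - 0.44));
    }
    // effect means (conjugate) and shared effect spreads
    {
      std::vector<double> col(M.N);
      for (int c = 0; c < 9; ++c) {
        for (int p = 0; p < M.N; ++p) col[p] = S.nueff[p][c];
        S.delta_nu[c] = gibbs_mean(col, S.sig_ne, 0.0, d_nu_sd, false);
        for (int p = 0; p < M.N; ++p) col[p] = S.aeff[p][c];
        S.delta_a[c] = gibbs_mean(col, S.sig_ae, 0.0, d_a_sd, false);
      }
      std::vector<double> xs(9 * M.N), mus(9 * M.N);
      for (int p = 0; p < M.N; ++p)
        for (int c = 0; c < 9; ++c) {
          xs[p * 9 + c] = S.nueff[p][c];
          mus[p * 9 + c] = S.delta_nu[c];
        }
      int a1 = mh_sigma(S.sig_ne, s_sne, xs, mus, sig_ne_sc);
      if (gain > 0) s_sne *= std::exp(gain * (a1 - 0.44));
      for (int p = 0; p < M.N; ++p)
        for (int c = 0; c < 9; ++c) {
          xs[p * 9 + c] = S.aeff[p][c];
          mus[p * 9 + c] = S.delta_a[c];
        }
      a1 = mh_sigma(S.sig_ae, s_sae, xs, mus, sig_ae_sc);
      if (gain > 0) s_sae *= std::exp(gain * (a1 - 0.44));
    }

    if (it >= n_burnin) {
      int r = it - n_burnin, j = 0;
      draws(r, j++) = S.mu_nu; draws(r, j++) = S.sig_nu;
      draws(r, j++) = S.mu_a; draws(r, j++) = S.sig_a;
      draws(r, j++) = S.mu_tp; draws(r, j++) = S.sig_tp;
      draws(r, j++) = S.mu_tm; draws(r, j++) = S.sig_tm;
      for (int c = 0; c < 9; ++c) draws(r, j++) = S.delta_nu[c];
      draws(r, j++) = S.sig_ne;
      for (int c = 0; c < 9; ++c) draws(r, j++) = S.delta_a[c];
      draws(r, j++) = S.sig_ae;
      for (int p = 0; p < M.N; ++p) {
        draws(r, j++) = S.nu[p]; draws(r, j++) = S.a[p];
        draws(r, j++) = S.tp[p]; draws(r, j++) = S.tm[p];
      }
      for (int p = 0; p < M.N; ++p)
        for (int c = 0; c < 9; ++c) draws(r, j++) = S.nueff[p][c];
      for (int p = 0; p < M.N; ++p)
        for (int c = 0; c < 9; ++c) draws(r, j++) = S.aeff[p][c];
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      Named("draws") = draws,
      Named("accept_joint") = wrap(acc_joint),
      Named("accept_tau_minus") = wrap(acc_tm));
}
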