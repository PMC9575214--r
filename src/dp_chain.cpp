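// Dirichlet-process edge covariance sampler: Gibbs sweep over node cluster
// assignments and Metropolis-Hastings updates of the correlation factors.
// The E x E structure Lambda is never formed; the likelihood term
// -N/2 (log|Lambda| + tr(H Lambda^{-1})) is evaluated in closed form from
// the block equicorrelation decomposition Lambda = A + rho0 * 1 1'.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// omega: 0-based contiguous labels 0..K-1. pairs: E x 2, 0-based node ids.
// Blocks of a single edge carry no rho_k constraint and are folded into the
// "between" set (their A entry is 1 - rho0 either way).
static double loglik_term(const arma::mat& H, const arma::imat& pairs,
                          const std::vector<int>& omega, int K,
                          double rho0, const std::vector<double>& rhok,
                          double N) {
  const int E = H.n_rows;
  std::vector<std::vector<int>> block(K);
  for (int e = 0; e < E; ++e) {
    int i = pairs(e, 0), j = pairs(e, 1);
    if (omega[i] == omega[j]) block[omega[i]].push_back(e);
  }
  std::vector<int> eff(E, -1); // effective block, -1 = between
  for (int k = 0; k < K; ++k) {
    if ((int)block[k].size() >= 2) {
      for (int e : block[k]) eff[e] = k;
    }
  }
  int n0 = 0;
  double T0 = 0.0;
  for (int e = 0; e < E; ++e) {
    if (eff[e] < 0) {
      ++n0;
      T0 += H(e, e);
    }
  }
  double one_m_r0 = 1.0 - rho0;
  if (n0 > 0 && one_m_r0 <= 0.0) return NEG_INF;
  double logdetA = (n0 > 0) ? n0 * std::log(one_m_r0) : 0.0;
  double trHA = (n0 > 0) ? T0 / one_m_r0 : 0.0;
  double s = (n0 > 0) ? n0 / one_m_r0 : 0.0;
  arma::vec u(E);
  u.fill(n0 > 0 ? 1.0 / one_m_r0 : 0.0);
  for (int k = 0; k < K; ++k) {
    int nk = (int)block[k].size();
    if (nk < 2 || eff[block[k][0]] < 0) continue;
    double ck = rhok[k] - rho0;
    double d1 = 1.0 - rhok[k];
    double lam2 = d1 + nk * ck;
    if (d1 <= 0.0 || lam2 <= 0.0) return NEG_INF;
    logdetA += (nk - 1) * std::log(d1) + std::log(lam2);
    double ak = 1.0 / d1, bk = -ck / (d1 * lam2);
    double Tk = 0.0, Sk = 0.0;
    for (int a : block[k]) {
      Tk += H(a, a);
      for (int b : block[k]) Sk += H(a, b);
    }
    trHA += ak * Tk + bk * Sk;
    double uk = 1.0 / lam2;
    s += nk * uk;
    for (int e : block[k]) u[e] = uk;
  }
  double denom = 1.0 + rho0 * s;
  if (denom <= 0.0) return NEG_INF;
  double logdet = logdetA + std::log(denom);
  double trHL = trHA;
  if (rho0 != 0.0) {
    double q = arma::dot(u, H * u);
    trHL -= rho0 * q / denom;
  }
  return -0.5 * N * (logdet + trHL);
}

static double crp_log_prior(const std::vector<int>& omega, int K,
                            double alpha) {
  int V = omega.size();
  std::vector<int> m(K, 0);
  for (int o : omega) m[o]++;
  double lp = K * std::log(alpha);
  for (int k = 0; k < K; ++k) lp += std::lgamma((double)m[k]);
  for (int i = 0; i < V; ++i) lp -= std::log(alpha + i);
  return lp;
}

// Relabel to first-occurrence order; permutes rhok accordingly.
static void canonicalize(std::vector<int>& omega, int& K,
                         std::vector<double>& rhok) {
  std::vector<int> newlab(K, -1);
  std::vector<double> newrho;
  newrho.reserve(K);
  int next = 0;
  for (size_t i = 0; i < omega.size(); ++i) {
    int o = omega[i];
    if (newlab[o] < 0) {
      newlab[o] = next++;
      newrho.push_back(rhok[o]);
    }
    omega[i] = newlab[o];
  }
  K = next;
  rhok = newrho;
}

// [[Rcpp::export]]
double dp_loglik_term_cpp(const arma::mat& H, const arma::imat& pairs,
                          const IntegerVector& omega, double rho0,
                          const NumericVector& rhok, double N) {
  std::vector<int> om(omega.size());
  int K = 0;
  for (int i = 0; i < omega.size(); ++i) {
    om[i] = omega[i] - 1;
    K = std::max(K, omega[i]);
  }
  std::vector<double> rk(rhok.begin(), rhok.end());
  if ((int)rk.size() < K) stop("rhok shorter than the number of clusters");
  return loglik_term(H, pairs, om, K, rho0, rk, N);
}

// [[Rcpp::export]]
List run_dp_chain_cpp(const arma::mat& H, const arma::imat& pairs, double N,
                      double alpha, double mu0, double tau0_sq, double muk,
                      double tauk_sq, double proposal_sd, int n_iter,
                      int n_burn, const IntegerVector& omega_init,
                      double rho0_init, double rhok_init) {
  const int E = H.n_rows;
  const int V = omega_init.size();
  if ((int)pairs.n_rows != E) stop("pairs/H dimension mismatch");
  std::vector<int> omega(V);
  int K = 0;
  for (int i = 0; i < V; ++i) {
    omega[i] = omega_init[i];
    K = std::max(K, omega[i] + 1);
  }
  std::vector<double> rhok(K, rhok_init);
  double rho0 = rho0_init;
  const double tau0 = std::sqrt(tau0_sq), tauk = std::sqrt(tauk_sq);

  const int n_keep = n_iter - n_burn;
  IntegerMatrix omega_draws(n_keep, V);
  NumericVector rho0_draws(n_keep);
  NumericVector logpost(n_keep);
  IntegerVector Kvec(n_keep);
  IntegerVector K_traj(n_iter);
  NumericVector logpost_traj(n_iter);
  std::vector<std::vector<double>> rhok_store(n_keep);
  int n_stuck = 0;
  long acc = 0, prop_cnt = 0;

  double ll_cur = loglik_term(H, pairs, omega, K, rho0, rhok, N);

  for (int iter = 0; iter < n_iter; ++iter) {
    // --- Gibbs sweep over nodes, ascending order ---
    for (int i = 0; i < V; ++i) {
      std::vector<int> m(K, 0);
      for (int j = 0; j < V; ++j) {
        if (j != i) m[omega[j]]++;
      }
      bool singleton = (m[omega[i]] == 0);
      double rho_new = singleton ? rhok[omega[i]]
                                 : R::rnorm(muk, tauk);
      std::vector<int> cand;
      for (int k = 0; k < K; ++k) {
        if (m[k] > 0) cand.push_back(k);
      }
      cand.push_back(-1); // new cluster
      int nc = cand.size();
      std::vector<double> logw(nc, NEG_INF);
      std::vector<double> llv(nc, NEG_INF);
      for (int c = 0; c < nc; ++c) {
        std::vector<int> om = omega;
        std::vector<double> rk = rhok;
        int Kt = K;
        if (cand[c] < 0) {
          if (singleton) {
            om[i] = omega[i]; // stay alone with current factor
          } else {
            om[i] = Kt;
            rk.push_back(rho_new);
            ++Kt;
          }
        } else {
          om[i] = cand[c];
        }
        double ll = loglik_term(H, pairs, om, Kt, rho0, rk, N);
        llv[c] = ll;
        if (std::isfinite(ll)) {
          logw[c] = ll + (cand[c] < 0 ? std::log(alpha)
                                      : std::log((double)m[cand[c]]));
        }
      }
      double mx = NEG_INF;
      for (double w : logw) mx = std::max(mx, w);
      if (!std::isfinite(mx)) {
        ++n_stuck;
        continue;
      }
      double tot = 0.0;
      std::vector<double> w(nc);
      for (int c = 0; c < nc; ++c) {
        w[c] = std::isfinite(logw[c]) ? std::exp(logw[c] - mx) : 0.0;
        tot += w[c];
      }
      double udraw = unif_rand() * tot;
      int pick = nc - 1;
      double cum = 0.0;
      for (int c = 0; c < nc; ++c) {
        cum += w[c];
        if (udraw <= cum) {
          pick = c;
          break;
        }
      }
      int old = omega[i];
      if (cand[pick] < 0) {
        if (!singleton) {
          omega[i] = K;
          rhok.push_back(rho_new);
          ++K;
        } // singleton stays put
      } else {
        omega[i] = cand[pick];
      }
      ll_cur = llv[pick];
      // remove emptied cluster
      bool occupied = false;
      for (int j = 0; j < V; ++j) {
        if (omega[j] == old) {
          occupied = true;
          break;
        }
      }
      if (!occupied) {
        for (int j = 0; j < V; ++j) {
          if (omega[j] > old) omega[j]--;
        }
        rhok.erase(rhok.begin() + old);
        --K;
      }
    }
    // --- MH updates of rho0 and each rho_k ---
    {
      ++prop_cnt;
      double prop = rho0 + norm_rand() * proposal_sd;
      double ll_prop = loglik_term(H, pairs, omega, K, prop, rhok, N);
      if (std::isfinite(ll_prop)) {
        double log_r = (ll_prop - ll_cur) +
                       R::dnorm(prop, mu0, tau0, 1) -
                       R::dnorm(rho0, mu0, tau0, 1);
        if (std::log(unif_rand()) < log_r) {
          rho0 = prop;
          ll_cur = ll_prop;
          ++acc;
        }
      }
    }
    for (int k = 0; k < K; ++k) {
      ++prop_cnt;
      double old_rk = rhok[k];
      rhok[k] = old_rk + norm_rand() * proposal_sd;
      double ll_prop = loglik_term(H, pairs, omega, K, rho0, rhok, N);
      bool accept = false;
      if (std::isfinite(ll_prop)) {
        double log_r = (ll_prop - ll_cur) +
                       R::dnorm(rhok[k], muk, tauk, 1) -
                       R::dnorm(old_rk, muk, tauk, 1);
        if (std::log(unif_rand()) < log_r) accept = true;
      }
      if (accept) {
        ll_cur = ll_prop;
        ++acc;
      } else {
        rhok[k] = old_rk;
      }
    }
    canonicalize(omega, K, rhok);
    // log posterior kernel of the sweep's final state
    double lp = ll_cur + crp_log_prior(omega, K, alpha) +
                R::dnorm(rho0, mu0, tau0, 1);
    for (int k = 0; k < K; ++k) lp += R::dnorm(rhok[k], muk, tauk, 1);
    K_traj[iter] = K;
    logpost_traj[iter] = lp;
    if (iter >= n_burn) {
      int r = iter - n_burn;
      for (int j = 0; j < V; ++j) omega_draws(r, j) = omega[j] + 1;
      rho0_draws[r] = rho0;
      rhok_store[r] = rhok;
      Kvec[r] = K;
      logpost[r] = lp;
    }
  }
  int Kmax = 0;
  for (int r = 0; r < n_keep; ++r) {
    Kmax = std::max(Kmax, (int)rhok_store[r].size());
  }
  NumericMatrix rhok_draws(n_keep, Kmax);
  std::fill(rhok_draws.begin(), rhok_draws.end(), NA_REAL);
  for (int r = 0; r < n_keep; ++r) {
    for (size_t k = 0; k < rhok_store[r].size(); ++k) {
      rhok_draws(r, k) = rhok_store[r][k];
    }
  }
  return List::create(
      _["omega"] = omega_draws, _["rho0"] = rho0_draws,
      _["rho_k"] = rhok_draws, _["K"] = Kvec, _["logpost"] = logpost,
      _["K_traj"] = K_traj, _["logpost_traj"] = logpost_traj,
      _["acc_rate"] = prop_cnt > 0 ? (double)acc / prop_cnt : NA_REAL,
      _["n_stuck"] = n_stuck);
}
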