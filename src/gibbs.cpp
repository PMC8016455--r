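#include <Rcpp.h>
using namespace Rcpp;

// One Gibbs chain over standardized marginal effects with a spike-and-slab
// prior. The LD matrix is passed as a general column-compressed sparse
// matrix (both triangles stored) with unit diagonal. R's RNG is used
// throughout so set.seed() in R makes runs bit-reproducible.
//
// Per-variant sample sizes n_j replace the scalar n of the constant-n
// formulas; M stays the total variant count. The shrinkage ratio
// M*p/(n_j*h2) is capped to avoid 0 * Inf in degenerate corners.

static const double SHRINK_CAP = 1e12;

// residualized marginal effect from the cached R*beta product
static inline double btilde_cached(int j, const double* beta_hat,
                                   const double* rtb, const double* beta) {
  return beta_hat[j] - rtb[j] + beta[j];
}

// direct dot-product evaluation, skipping the diagonal
static inline double btilde_direct(int j, const double* beta_hat,
                                   const int* p, const int* i,
                                   const double* x, const double* beta) {
  double acc = 0.0;
  for (int k = p[j]; k < p[j + 1]; ++k) {
    if (i[k] != j) acc += x[k] * beta[i[k]];
  }
  return beta_hat[j] - acc;
}

// stable causal posterior probability; never overflows for large n*btilde^2
static inline double pbar_stable(double btilde, double pp, double h2,
                                 double nj, double M) {
  double ratio = M * pp / (nj * h2);
  if (ratio > SHRINK_CAP) ratio = SHRINK_CAP;
  double log_odds_null = std::log((1.0 - pp) / pp)
    + 0.5 * std::log1p(nj * h2 / (M * pp))
    - 0.5 * nj * btilde * btilde / (1.0 + ratio);
  if (log_odds_null > 700.0) return 0.0;
  return 1.0 / (1.0 + std::exp(log_odds_null));
}

// [[Rcpp::export(name = ".gibbs_chain_cpp")]]
List gibbs_chain_cpp(S4 Rsp, NumericVector beta_hat, NumericVector n_vec,
                     double M_total, double p_init, double h2_init,
                     bool sparse, bool auto_update, int burn_in, int num_iter,
                     std::string cache = "incremental", int refresh_every = 100,
                     double beta_div_limit = 10.0, double h2_div_limit = 1.5,
                     int h2_div_patience = 10) {
  IntegerVector Rp = Rsp.slot("p");
  IntegerVector Ri = Rsp.slot("i");
  NumericVector Rx = Rsp.slot("x");
  const int* pp_ = Rp.begin();
  const int* ii_ = Ri.begin();
  const double* xx_ = Rx.begin();
  int m = beta_hat.size();
  bool direct = (cache == "direct");

  std::vector<double> beta(m, 0.0), rtb(m, 0.0), omega(m, 0.0), Omega(m, 0.0);
  double p_cur = p_init, h2_cur = h2_init;
  int total = burn_in + num_iter;
  NumericVector p_traj(auto_update ? total : 0);
  NumericVector h2_traj(auto_update ? total : 0);
  bool diverged = false;
  int h2_high_streak = 0;

  RNGScope scope;

  for (int sweep = 0; sweep < total && !diverged; ++sweep) {
    if (!direct && refresh_every > 0 && sweep > 0 && sweep % refresh_every == 0) {
      std::fill(rtb.begin(), rtb.end(), 0.0);
      for (int j = 0; j < m; ++j) {
        double bj = beta[j];
        if (bj != 0.0) {
          for (int k = pp_[j]; k < pp_[j + 1]; ++k) rtb[ii_[k]] += xx_[k] * bj;
        }
      }
    }
    for (int j = 0; j < m; ++j) {
      double nj = n_vec[j];
      double bt = direct
        ? btilde_direct(j, beta_hat.begin(), pp_, ii_, xx_, beta.data())
        : btilde_cached(j, beta_hat.begin(), rtb.data(), beta.data());
      if (!std::isfinite(bt)) { diverged = true; break; }
      double pbar = pbar_stable(bt, p_cur, h2_cur, nj, M_total);
      double ratio = M_total * p_cur / (nj * h2_cur);
      if (ratio > SHRINK_CAP) ratio = SHRINK_CAP;
      double C = 1.0 + ratio;
      double beta_new, omega_j;
      if (sparse && pbar < p_cur) {
        beta_new = 0.0;
        omega_j = 0.0;
      } else {
        omega_j = pbar * bt / C;
        double u = R::unif_rand();
        if (u < pbar) {
          beta_new = bt / C + R::norm_rand() * std::sqrt(1.0 / (C * nj));
        } else {
          beta_new = 0.0;
        }
      }
      if (std::fabs(beta_new) > beta_div_limit) { diverged = true; break; }
      double delta = beta_new - beta[j];
      if (!direct && delta != 0.0) {
        for (int k = pp_[j]; k < pp_[j + 1]; ++k) rtb[ii_[k]] += xx_[k] * delta;
      }
      beta[j] = beta_new;
      omega[j] = omega_j;
    }
    if (diverged) break;

    if (auto_update) {
      int Mc = 0;
      for (int j = 0; j < m; ++j) if (beta[j] != 0.0) ++Mc;
      double p_new = R::rbeta(1.0 + Mc, 1.0 + M_total - Mc);
      if (p_new < 1e-10) p_new = 1e-10;
      if (p_new > 1.0 - 1e-10) p_new = 1.0 - 1e-10;
      // h2 = beta' R beta via the cached product (recomputed if direct)
      double h2_new = 0.0;
      if (direct) {
        for (int j = 0; j < m; ++j) {
          double bj = beta[j];
          if (bj == 0.0) continue;
          double acc = 0.0;
          for (int k = pp_[j]; k < pp_[j + 1]; ++k) acc += xx_[k] * beta[ii_[k]];
          h2_new += bj * acc;
        }
      } else {
        for (int j = 0; j < m; ++j) h2_new += beta[j] * rtb[j];
      }
      if (!std::isfinite(h2_new)) { diverged = true; break; }
      if (h2_new < 1e-4) h2_new = 1e-4;
      if (h2_new > h2_div_limit) {
        if (++h2_high_streak >= h2_div_patience) { diverged = true; }
      } else {
        h2_high_streak = 0;
      }
      p_cur = p_new;
      h2_cur = h2_new;
      p_traj[sweep] = p_cur;
      h2_traj[sweep] = h2_cur;
      if (diverged) break;
    }

    if (sweep >= burn_in) {
      for (int j = 0; j < m; ++j) Omega[j] += omega[j];
    }
  }

  NumericVector Omega_out(m), beta_out(m);
  if (!diverged) {
    for (int j = 0; j < m; ++j) {
      Omega_out[j] = Omega[j] / num_iter;
      beta_out[j] = beta[j];
    }
  } else {
    std::fill(Omega_out.begin(), Omega_out.end(), NA_REAL);
    std::fill(beta_out.begin(), beta_out.end(), NA_REAL);
  }
  return List::create(_["omega"] = Omega_out, _["beta"] = beta_out,
                      _["diverged"] = diverged,
                      _["p_traj"] = p_traj, _["h2_traj"] = h2_traj,
                      _["p_final"] = p_cur, _["h2_final"] = h2_cur);
}
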