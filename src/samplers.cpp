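#include <Rcpp.h>
using namespace Rcpp;

// Adaptive random-walk Metropolis-within-Gibbs samplers for
//  (1) the site-occupancy model with imperfect detection and an iCAR
//      spatial random effect on the ecological linear predictor, and
//  (2) the Bernoulli/binomial presence model with an iCAR effect.
// All randomness flows through R's RNG (RNGScope), so set.seed() in R
// makes chains fully deterministic.

static inline double loglp_exp(double x) {
  // numerically stable log(1 + exp(x))
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Bernoulli(z; invlogit(eta)) log-density
static inline double bern_ll(int z, double eta) {
  return z * eta - loglp_exp(eta);
}

// adapt a proposal scale toward the 0.44 per-scalar target
static inline void adapt_scale(double &s, int acc, int tries) {
  if (tries == 0) return;
  double rate = (double)acc / tries;
  s *= std::exp(rate - 0.44);
  if (s < 1e-4) s = 1e-4;
  if (s > 50.0) s = 50.0;
}

// [[Rcpp::export]]
List mcmc_siteocc_icar_cpp(NumericMatrix X, NumericMatrix W,
                           IntegerVector visit_cell, // 0-based
                           IntegerVector y,
                           List nb,                  // 0-based neighbour lists
                           IntegerVector comp_id,    // 0-based component per cell
                           double prior_var_coef,
                           double vrho_lower, double vrho_upper,
                           int n_iter, int burnin, int thin,
                           NumericVector beta_init, NumericVector gamma_init,
                           double vrho_init,
                           bool spatial,             // false -> rho frozen at 0
                           LogicalVector gamma_fixed // per-element: skip update
) {
  int n = X.nrow(), p = X.ncol(), q = W.ncol(), V = W.nrow();
  int ncomp = 0;
  for (int i = 0; i < n; ++i) if (comp_id[i] + 1 > ncomp) ncomp = comp_id[i] + 1;

  // per-cell visit bookkeeping
  std::vector<std::vector<int>> cell_visits(n);
  std::vector<int> detected(n, 0);
  for (int t = 0; t < V; ++t) {
    cell_visits[visit_cell[t]].push_back(t);
    if (y[t] == 1) detected[visit_cell[t]] = 1;
  }
  std::vector<int> ndeg(n);
  for (int i = 0; i < n; ++i) ndeg[i] = ((IntegerVector)nb[i]).size();

  // iCAR rank = n_nontrivial - n_components counted over cells with neighbours;
  // isolated cells have rho fixed at 0 and contribute nothing.
  int rankQ = 0;
  {
    std::vector<int> comp_size(ncomp, 0), comp_edges(ncomp, 0);
    for (int i = 0; i < n; ++i) if (ndeg[i] > 0) comp_size[comp_id[i]]++;
    for (int c = 0; c < ncomp; ++c) if (comp_size[c] > 1) rankQ += comp_size[c] - 1;
  }

  // state
  NumericVector beta = clone(beta_init), gamma = clone(gamma_init);
  double vrho = vrho_init;
  NumericVector rho(n, 0.0);
  IntegerVector z(n);
  NumericVector eta_occ(n), eta_det(V);
  for (int i = 0; i < n; ++i) {
    double e = 0; for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta_occ[i] = e + rho[i];
    z[i] = detected[i] ? 1 : (invlogit(eta_occ[i]) > 0.5 ? 1 : 0);
  }
  for (int t = 0; t < V; ++t) {
    double e = 0; for (int j = 0; j < q; ++j) e += W(t, j) * gamma[j];
    eta_det[t] = e;
  }

  // proposal scales + acceptance counters
  std::vector<double> s_beta(p, 0.5), s_gamma(q, 0.5), s_rho(n, 0.5);
  double s_vrho = 0.5;
  std::vector<int> a_beta(p, 0), t_beta(p, 0), a_gamma(q, 0), t_gamma(q, 0);
  std::vector<int> a_rho(n, 0), t_rho(n, 0);
  int a_vrho = 0, t_vrho = 0;
  // post-burn-in acceptance tallies
  std::vector<long> A_beta(p, 0), A_gamma(q, 0), A_rho(n, 0);
  long A_vrho = 0, kept_iters = 0;

  int n_keep = (n_iter - burnin + thin - 1) / thin;
  if (n_keep < 0) n_keep = 0;
  NumericMatrix beta_draws(n_keep, p), gamma_draws(n_keep, q);
  NumericMatrix rho_draws(n_keep, n);
  NumericVector vrho_draws(n_keep);
  IntegerMatrix z_draws(n_keep, n);
  int keep = 0;

  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    bool adapting = it < burnin;

    // --- z | rest (Gibbs) ------------------------------------------------
    for (int i = 0; i < n; ++i) {
      if (detected[i]) { z[i] = 1; continue; }
      double pi = invlogit(eta_occ[i]);
      double lp_nodet = 0.0; // log prod_t (1 - delta_it)
      for (int t : cell_visits[i]) lp_nodet += -loglp_exp(eta_det[t]);
      double p1 = pi * std::exp(lp_nodet);
      double pr = p1 / (p1 + (1.0 - pi));
      z[i] = (unif_rand() < pr) ? 1 : 0;
    }

    // --- beta (scalar RW-MH) ---------------------------------------------
    for (int j = 0; j < p; ++j) {
      double prop = beta[j] + s_beta[j] * norm_rand();
      double dlp = (beta[j] * beta[j] - prop * prop) / (2.0 * prior_var_coef);
      double d = prop - beta[j];
      for (int i = 0; i < n; ++i) {
        double e_new = eta_occ[i] + d * X(i, j);
        dlp += bern_ll(z[i], e_new) - bern_ll(z[i], eta_occ[i]);
      }
      t_beta[j]++;
      if (std::log(unif_rand()) < dlp) {
        for (int i = 0; i < n; ++i) eta_occ[i] += d * X(i, j);
        beta[j] = prop;
        a_beta[j]++; if (!adapting) A_beta[j]++;
      }
      if (adapting && t_beta[j] == 50) {
        adapt_scale(s_beta[j], a_beta[j], 50); a_beta[j] = 0; t_beta[j] = 0;
      }
    }

    // --- gamma (scalar RW-MH; likelihood over visits in occupied cells) --
    for (int j = 0; j < q; ++j) {
      if (gamma_fixed[j]) continue;
      double prop = gamma[j] + s_gamma[j] * norm_rand();
      double dlp = (gamma[j] * gamma[j] - prop * prop) / (2.0 * prior_var_coef);
      double d = prop - gamma[j];
      for (int t = 0; t < V; ++t) {
        if (!z[visit_cell[t]]) continue;
        double e_new = eta_det[t] + d * W(t, j);
        dlp += bern_ll(y[t], e_new) - bern_ll(y[t], eta_det[t]);
      }
      t_gamma[j]++;
      if (std::log(unif_rand()) < dlp) {
        for (int t = 0; t < V; ++t) eta_det[t] += d * W(t, j);
        gamma[j] = prop;
        a_gamma[j]++; if (!adapting) A_gamma[j]++;
      }
      if (adapting && t_gamma[j] == 50) {
        adapt_scale(s_gamma[j], a_gamma[j], 50); a_gamma[j] = 0; t_gamma[j] = 0;
      }
    }

    if (spatial) {
      // --- rho_i (scalar RW-MH against iCAR full-conditional prior) ------
      for (int i = 0; i < n; ++i) {
        if (ndeg[i] == 0) continue; // isolated cell: rho fixed at 0
        IntegerVector nbi = nb[i];
        double mn = 0.0;
        for (int k = 0; k < ndeg[i]; ++k) mn += rho[nbi[k]];
        mn /= ndeg[i];
        double prec = ndeg[i] / vrho;
        double prop = rho[i] + s_rho[i] * norm_rand();
        double dlp = 0.5 * prec *
          ((rho[i] - mn) * (rho[i] - mn) - (prop - mn) * (prop - mn));
        double e_new = eta_occ[i] + (prop - rho[i]);
        dlp += bern_ll(z[i], e_new) - bern_ll(z[i], eta_occ[i]);
        t_rho[i]++;
        if (std::log(unif_rand()) < dlp) {
          eta_occ[i] = e_new; rho[i] = prop;
          a_rho[i]++; if (!adapting) A_rho[i]++;
        }
        if (adapting && t_rho[i] == 50) {
          adapt_scale(s_rho[i], a_rho[i], 50); a_rho[i] = 0; t_rho[i] = 0;
        }
      }

      // --- recenter rho per connected component --------------------------
      {
        std::vector<double> cm(ncomp, 0.0); std::vector<int> cn(ncomp, 0);
        for (int i = 0; i < n; ++i) if (ndeg[i] > 0) {
          cm[comp_id[i]] += rho[i]; cn[comp_id[i]]++;
        }
        for (int c = 0; c < ncomp; ++c) if (cn[c] > 0) cm[c] /= cn[c];
        for (int i = 0; i < n; ++i) if (ndeg[i] > 0) {
          eta_occ[i] -= cm[comp_id[i]];
          rho[i] -= cm[comp_id[i]];
        }
      }

      // --- V_rho (log-scale RW-MH, Uniform(vrho_lower, vrho_upper) prior)
      {
        double S = 0.0; // rho' Q rho = sum over edges (rho_i - rho_j)^2
        for (int i = 0; i < n; ++i) {
          IntegerVector nbi = nb[i];
          for (int k = 0; k < ndeg[i]; ++k) {
            int j = nbi[k];
            if (j > i) { double d = rho[i] - rho[j]; S += d * d; }
          }
        }
        double lv = std::log(vrho);
        double lv_prop = lv + s_vrho * norm_rand();
        double v_prop = std::exp(lv_prop);
        t_vrho++;
        if (v_prop > vrho_lower && v_prop < vrho_upper) {
          // log p(rho|v) = -(rank/2) log v - S/(2v); + log-Jacobian lv
          double dlp = -(rankQ / 2.0) * (lv_prop - lv)
                       - S / 2.0 * (1.0 / v_prop - 1.0 / vrho)
                       + (lv_prop - lv);
          if (std::log(unif_rand()) < dlp) {
            vrho = v_prop; a_vrho++; if (!adapting) A_vrho++;
          }
        }
        if (adapting && t_vrho == 50) {
          adapt_scale(s_vrho, a_vrho, 50); a_vrho = 0; t_vrho = 0;
        }
      }
    }

    // --- store -----------------------------------------------------------
    if (it >= burnin) {
      kept_iters++;
      if ((it - burnin) % thin == 0 && keep < n_keep) {
        for (int j = 0; j < p; ++j) beta_draws(keep, j) = beta[j];
        for (int j = 0; j < q; ++j) gamma_draws(keep, j) = gamma[j];
        for (int i = 0; i < n; ++i) {
          rho_draws(keep, i) = rho[i];
          z_draws(keep, i) = z[i];
        }
        vrho_draws[keep] = vrho;
        keep++;
      }
    }
  }

  double denom = kept_iters > 0 ? (double)kept_iters : 1.0;
  NumericVector acc_beta(p), acc_gamma(q);
  for (int j = 0; j < p; ++j) acc_beta[j] = A_beta[j] / denom;
  for (int j = 0; j < q; ++j) acc_gamma[j] = A_gamma[j] / denom;
  double acc_rho_mean = 0; int nr = 0;
  for (int i = 0; i < n; ++i) if (ndeg[i] > 0) { acc_rho_mean += A_rho[i] / denom; nr++; }
  if (nr > 0) acc_rho_mean /= nr;

  return List::create(
    _["beta"] = beta_draws, _["gamma"] = gamma_draws,
    _["rho"] = rho_draws, _["Vrho"] = vrho_draws, _["z"] = z_draws,
    _["acc_beta"] = acc_beta, _["acc_gamma"] = acc_gamma,
    _["acc_rho"] = acc_rho_mean, _["acc_Vrho"] = A_vrho / denom);
}

// [[Rcpp::export]]
List mcmc_binomial_icar_cpp(NumericMatrix X, IntegerVector trials,
                            IntegerVector succ,
                            List nb, IntegerVector comp_id,
                            double prior_var_coef,
                            double vrho_lower, double vrho_upper,
                            int n_iter, int burnin, int thin,
                            NumericVector beta_init, double vrho_init,
                            bool spatial) {
  int n = X.nrow(), p = X.ncol();
  int ncomp = 0;
  for (int i = 0; i < n; ++i) if (comp_id[i] + 1 > ncomp) ncomp = comp_id[i] + 1;
  std::vector<int> ndeg(n);
  for (int i = 0; i < n; ++i) ndeg[i] = ((IntegerVector)nb[i]).size();
  int rankQ = 0;
  {
    std::vector<int> comp_size(ncomp, 0);
    for (int i = 0; i < n; ++i) if (ndeg[i] > 0) comp_size[comp_id[i]]++;
    for (int c = 0; c < ncomp; ++c) if (comp_size[c] > 1) rankQ += comp_size[c] - 1;
  }

  NumericVector beta = clone(beta_init);
  double vrho = vrho_init;
  NumericVector rho(n, 0.0), eta(n);
  for (int i = 0; i < n; ++i) {
    double e = 0; for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta[i] = e;
  }

  auto binom_ll = [&](int i, double e) {
    return succ[i] * e - trials[i] * loglp_exp(e);
  };

  std::vector<double> s_beta(p, 0.5), s_rho(n, 0.5);
  double s_vrho = 0.5;
  std::vector<int> a_beta(p, 0), t_beta(p, 0), a_rho(n, 0), t_rho(n, 0);
  int a_vrho = 0, t_vrho = 0;
  std::vector<long> A_beta(p, 0), A_rho(n, 0);
  long A_vrho = 0, kept_iters = 0;

  int n_keep = (n_iter - burnin + thin - 1) / thin;
  if (n_keep < 0) n_keep = 0;
  NumericMatrix beta_draws(n_keep, p), rho_draws(n_keep, n);
  NumericVector vrho_draws(n_keep);
  int keep = 0;

  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    bool adapting = it < burnin;

    for (int j = 0; j < p; ++j) {
      double prop = beta[j] + s_beta[j] * norm_rand();
      double dlp = (beta[j] * beta[j] - prop * prop) / (2.0 * prior_var_coef);
      double d = prop - beta[j];
      for (int i = 0; i < n; ++i)
        dlp += binom_ll(i, eta[i] + d * X(i, j)) - binom_ll(i, eta[i]);
      t_beta[j]++;
      if (std::log(unif_rand()) < dlp) {
        for (int i = 0; i < n; ++i) eta[i] += d * X(i, j);
        beta[j] = prop;
        a_beta[j]++; if (!adapting) A_beta[j]++;
      }
      if (adapting && t_beta[j] == 50) {
        adapt_scale(s_beta[j], a_beta[j], 50); a_beta[j] = 0; t_beta[j] = 0;
      }
    }

    if (spatial) {
      for (int i = 0; i < n; ++i) {
        if (ndeg[i] == 0) continue;
        IntegerVector nbi = nb[i];
        double mn = 0.0;
        for (int k = 0; k < ndeg[i]; ++k) mn += rho[nbi[k]];
        mn /= ndeg[i];
        double prec = ndeg[i] / vrho;
        double prop = rho[i] + s_rho[i] * norm_rand();
        double dlp = 0.5 * prec *
          ((rho[i] - mn) * (rho[i] - mn) - (prop - mn) * (prop - mn));
        dlp += binom_ll(i, eta[i] + (prop - rho[i])) - binom_ll(i, eta[i]);
        t_rho[i]++;
        if (std::log(unif_rand()) < dlp) {
          eta[i] += prop - rho[i]; rho[i] = prop;
          a_rho[i]++; if (!adapting) A_rho[i]++;
        }
        if (adapting && t_rho[i] == 50) {
          adapt_scale(s_rho[i], a_rho[i], 50); a_rho[i] = 0; t_rho[i] = 0;
        }
      }
      {
        std::vector<double> cm(ncomp, 0.0); std::vector<int> cn(ncomp, 0);
        for (int i = 0; i < n; ++i) if (ndeg[i] > 0) {
          cm[comp_id[i]] += rho[i]; cn[comp_id[i]]++;
        }
        for (int c = 0; c < ncomp; ++c) if (cn[c] > 0) cm[c] /= cn[c];
        for (int i = 0; i < n; ++i) if (ndeg[i] > 0) {
          eta[i] -= cm[comp_id[i]]; rho[i] -= cm[comp_id[i]];
        }
      }
      {
        double S = 0.0;
        for (int i = 0; i < n; ++i) {
          IntegerVector nbi = nb[i];
          for (int k = 0; k < ndeg[i]; ++k) {
            int j = nbi[k];
            if (j > i) { double d = rho[i] - rho[j]; S += d * d; }
          }
        }
        double lv = std::log(vrho);
        double lv_prop = lv + s_vrho * norm_rand();
        double v_prop = std::exp(lv_prop);
        t_vrho++;
        if (v_prop > vrho_lower && v_prop < vrho_upper) {
          double dlp = -(rankQ / 2.0) * (lv_prop - lv)
                       - S / 2.0 * (1.0 / v_prop - 1.0 / vrho)
                       + (lv_prop - lv);
          if (std::log(unif_rand()) < dlp) {
            vrho = v_prop; a_vrho++; if (!adapting) A_vrho++;
          }
        }
        if (adapting && t_vrho == 50) {
          adapt_scale(s_vrho, a_vrho, 50); a_vrho = 0; t_vrho = 0;
        }
      }
    }

    if (it >= burnin) {
      kept_iters++;
      if ((it - burnin) % thin == 0 && keep < n_keep) {
        for (int j = 0; j < p; ++j) beta_draws(keep, j) = beta[j];
        for (int i = 0; i < n; ++i) rho_draws(keep, i) = rho[i];
        vrho_draws[keep] = vrho;
        keep++;
      }
    }
  }

  double denom = kept_iters > 0 ? (double)kept_iters : 1.0;
  NumericVector acc_beta(p);
  for (int j = 0; j < p; ++j) acc_beta[j] = A_beta[j] / denom;
  double acc_rho_mean = 0; int nr = 0;
  for (int i = 0; i < n; ++i) if (ndeg[i] > 0) { acc_rho_mean += A_rho[i] / denom; nr++; }
  if (nr > 0) acc_rho_mean /= nr;

  return List::create(
    _["beta"] = beta_draws, _["rho"] = rho_draws, _["Vrho"] = vrho_draws,
    _["acc_beta"] = acc_beta, _["acc_rho"] = acc_rho_mean,
    _["acc_Vrho"] = A_vrho / denom);
}
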