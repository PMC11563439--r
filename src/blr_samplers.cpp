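// Gibbs samplers for the spike-and-slab (BayesC) gene-set models.
// R's RNG is used throughout (via Rcpp's RNGScope) so set.seed() in R
// makes every run reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// scaled inverse chi-square draw: sigma2 ~ (nu*S + ss) / chisq(nu + k)
static inline double rinvchisq(double nu, double S, double ss, double k) {
  return (nu * S + ss) / R::rchisq(nu + k);
}

// Single-trait BayesC: y = X b + e, b_j in {0, N(0, sb2)} w.p. {1-pi, pi}.
// Single-site updates in fixed column order; the inclusion indicator is
// sampled with b_j marginalized (collapsed within site).
// [[Rcpp::export]]
List blr_single_gibbs(const arma::vec& y, const arma::mat& X,
                      int n_iter, int burn_in,
                      double pi_init, bool estimate_pi,
                      double alpha1, double alpha2,
                      double nu_b, double S_b, bool est_sb, double sb2_init,
                      double nu_e, double S_e, bool est_se, double se2_init,
                      bool keep_samples) {
  const int n = X.n_rows, m = X.n_cols;
  arma::vec c(m);
  for (int j = 0; j < m; ++j) c(j) = arma::dot(X.col(j), X.col(j));

  arma::vec b(m, arma::fill::zeros);
  arma::ivec d(m, arma::fill::zeros);
  arma::vec r = y;                       // residual y - X b
  double sb2 = sb2_init, se2 = se2_init, pi = pi_init;

  const int n_keep = n_iter - burn_in;
  arma::vec pip(m, arma::fill::zeros), bsum(m, arma::fill::zeros);
  arma::vec sb2_s(n_keep), se2_s(n_keep), pi_s(n_keep);
  arma::mat B_keep;
  if (keep_samples) B_keep.set_size(n_keep, m);

  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < m; ++j) {
      const double rhs = arma::dot(X.col(j), r) + c(j) * b(j);
      const double v0 = c(j) * se2;
      const double v1 = v0 + c(j) * c(j) * sb2;
      const double logBF = 0.5 * std::log(v0 / v1)
        + 0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
      const double logit = std::log(pi) - std::log1p(-pi) + logBF;
      double p1;
      if (logit > 35.0) p1 = 1.0;
      else if (logit < -35.0) p1 = 0.0;
      else p1 = 1.0 / (1.0 + std::exp(-logit));
      const double b_old = b(j);
      double b_new = 0.0;
      int d_new = (unif_rand() < p1) ? 1 : 0;
      if (d_new == 1) {
        const double prec = c(j) + se2 / sb2;
        b_new = rhs / prec + R::norm_rand() * std::sqrt(se2 / prec);
      }
      if (b_new != b_old) r += X.col(j) * (b_old - b_new);
      b(j) = b_new;
      d(j) = d_new;
    }
    const int m1 = arma::accu(d);
    if (est_sb) {
      const double ssb = arma::dot(b, b);  // zeros contribute nothing
      sb2 = rinvchisq(nu_b, S_b, ssb, (double)m1);
    }
    if (est_se) se2 = rinvchisq(nu_e, S_e, arma::dot(r, r), (double)n);
    if (estimate_pi) pi = R::rbeta(m1 + alpha1, m - m1 + alpha2);

    if (it >= burn_in) {
      const int k = it - burn_in;
      for (int j = 0; j < m; ++j) { pip(j) += d(j); bsum(j) += b(j); }
      sb2_s(k) = sb2; se2_s(k) = se2; pi_s(k) = pi;
      if (keep_samples) B_keep.row(k) = b.t();
    }
  }
  pip /= n_keep; bsum /= n_keep;
  List out = List::create(
    Named("pip") = pip, Named("b_mean") = bsum,
    Named("sigma_b2") = sb2_s, Named("sigma_e2") = se2_s,
    Named("pi") = pi_s);
  if (keep_samples) out["b_samples"] = B_keep;
  return out;
}

// lower-triangular Bartlett factor for a Wishart(df, Sigma = LL') draw
static arma::mat bartlett_lower(int t, double df) {
  arma::mat A(t, t, arma::fill::zeros);
  for (int i = 0; i < t; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  return A;
}

// V ~ InverseWishart(S, df): V = W^{-1} with W ~ Wishart(S^{-1}, df)
static arma::mat riwish(const arma::mat& S, double df) {
  arma::mat Sinv = arma::inv_sympd(S);
  arma::mat L = arma::chol(Sinv, "lower");
  arma::mat A = bartlett_lower(S.n_rows, df);
  arma::mat LA = L * A;
  arma::mat W = LA * LA.t();
  return arma::inv_sympd(W);
}

// Multi-trait BayesC with per-set trait-configuration indicators.
// Rows of the residual matrix are iid N(0, V_E); a set's effect vector is
// N(0, V_B) on its active traits and zero elsewhere. Configurations are
// sampled with the active effects integrated out.
// [[Rcpp::export]]
List blr_multi_gibbs(const arma::mat& Y, const arma::mat& X,
                     int n_iter, int burn_in,
                     double pi_init, bool estimate_pi, bool combination,
                     bool diagonal_cov,
                     const arma::mat& S_B, double nu_B, bool est_VB,
                     const arma::mat& VB_init,
                     const arma::mat& S_E, double nu_E, bool est_VE,
                     const arma::mat& VE_init,
                     const arma::vec& Sb_diag, double nub_diag,
                     const arma::vec& Se_diag, double nue_diag,
                     bool keep_samples) {
  const int n = X.n_rows, m = X.n_cols, t = Y.n_cols;
  const int ncfg = 1 << t;
  arma::vec c(m);
  for (int j = 0; j < m; ++j) c(j) = arma::dot(X.col(j), X.col(j));

  // enumerate configurations as bit patterns
  std::vector<arma::uvec> active(ncfg);
  for (int cfg = 0; cfg < ncfg; ++cfg) {
    std::vector<unsigned int> a;
    for (int s = 0; s < t; ++s) if (cfg & (1 << s)) a.push_back(s);
    active[cfg] = arma::uvec(a);
  }

  arma::mat B(m, t, arma::fill::zeros);       // effective effects (0 if inactive)
  arma::imat D(m, t, arma::fill::zeros);
  arma::ivec cfg_of(m, arma::fill::zeros);
  arma::mat Rres = Y;                          // residual Y - X B
  arma::mat VB = VB_init, VE = VE_init;
  arma::vec pi_t(t, arma::fill::value(pi_init));
  arma::vec pcfg(ncfg);
  for (int cfg = 0; cfg < ncfg; ++cfg) {
    double lp = 0.0;
    for (int s = 0; s < t; ++s)
      lp += (cfg & (1 << s)) ? std::log(pi_init) : std::log1p(-pi_init);
    pcfg(cfg) = std::exp(lp);
  }

  const int n_keep = n_iter - burn_in;
  arma::mat pip(m, t, arma::fill::zeros), Bsum(m, t, arma::fill::zeros);
  arma::vec pip_any(m, arma::fill::zeros);
  arma::mat VBsum(t, t, arma::fill::zeros), VEsum(t, t, arma::fill::zeros);
  arma::mat VBd_s(n_keep, t), VEd_s(n_keep, t);
  arma::mat B_keep;
  if (keep_samples) B_keep.set_size(n_keep, m * t);

  std::vector<arma::mat> VEinv_aa(ncfg), VBinv_aa(ncfg);
  std::vector<double> logdetVB_aa(ncfg);
  arma::vec logprior(ncfg);
  const bool enumerate_all = (t <= 5);

  for (int it = 0; it < n_iter; ++it) {
    arma::mat VEinv = arma::inv_sympd(VE);
    for (int cfg = 1; cfg < ncfg; ++cfg) {
      const arma::uvec& a = active[cfg];
      VEinv_aa[cfg] = VEinv.submat(a, a);
      arma::mat VBaa = VB.submat(a, a);
      VBinv_aa[cfg] = arma::inv_sympd(VBaa);
      double val, sign;
      arma::log_det(val, sign, VBaa);
      logdetVB_aa[cfg] = val;
    }
    for (int cfg = 0; cfg < ncfg; ++cfg) {
      if (combination) {
        logprior(cfg) = std::log(std::max(pcfg(cfg), 1e-300));
      } else {
        double lp = 0.0;
        for (int s = 0; s < t; ++s)
          lp += (cfg & (1 << s)) ? std::log(pi_t(s)) : std::log1p(-pi_t(s));
        logprior(cfg) = lp;
      }
    }

    for (int j = 0; j < m; ++j) {
      arma::vec rhs = Rres.t() * X.col(j);
      rhs += c(j) * B.row(j).t();
      arma::vec eta_full = VEinv * rhs;

      // log marginal weight of a configuration (active effects integrated)
      auto logml = [&](int cfg) -> double {
        if (cfg == 0) return 0.0;
        const arma::uvec& a = active[cfg];
        arma::mat P = c(j) * VEinv_aa[cfg] + VBinv_aa[cfg];
        arma::mat U = arma::chol(P);
        double logdetP = 2.0 * arma::accu(arma::log(U.diag()));
        arma::vec eta = eta_full.elem(a);
        arma::vec u = arma::solve(arma::trimatl(U.t()), eta);
        return -0.5 * logdetVB_aa[cfg] - 0.5 * logdetP + 0.5 * arma::dot(u, u);
      };

      int cfg_new;
      if (enumerate_all) {
        arma::vec lw(ncfg);
        for (int cfg = 0; cfg < ncfg; ++cfg) lw(cfg) = logprior(cfg) + logml(cfg);
        lw -= lw.max();
        arma::vec w = arma::exp(lw);
        w /= arma::accu(w);
        double u = unif_rand(), acc = 0.0;
        cfg_new = ncfg - 1;
        for (int cfg = 0; cfg < ncfg; ++cfg) {
          acc += w(cfg);
          if (u <= acc) { cfg_new = cfg; break; }
        }
      } else {
        // componentwise collapsed update of each trait's indicator
        cfg_new = cfg_of(j);
        for (int s = 0; s < t; ++s) {
          int cfg0 = cfg_new & ~(1 << s);
          int cfg1 = cfg_new | (1 << s);
          double l0 = logprior(cfg0) + logml(cfg0);
          double l1 = logprior(cfg1) + logml(cfg1);
          double p1 = 1.0 / (1.0 + std::exp(l0 - l1));
          cfg_new = (unif_rand() < p1) ? cfg1 : cfg0;
        }
      }

      arma::vec b_old = B.row(j).t();
      arma::vec b_new(t, arma::fill::zeros);
      if (cfg_new != 0) {
        const arma::uvec& a = active[cfg_new];
        arma::mat P = c(j) * VEinv_aa[cfg_new] + VBinv_aa[cfg_new];
        arma::mat U = arma::chol(P);
        arma::vec eta = eta_full.elem(a);
        arma::vec mu = arma::solve(arma::trimatu(U),
                                   arma::solve(arma::trimatl(U.t()), eta));
        arma::vec z(a.n_elem);
        for (unsigned int q = 0; q < a.n_elem; ++q) z(q) = R::norm_rand();
        arma::vec ba = mu + arma::solve(arma::trimatu(U), z);
        b_new.elem(a) = ba;
      }
      arma::vec diff = b_old - b_new;
      if (arma::any(diff != 0.0)) Rres += X.col(j) * diff.t();
      B.row(j) = b_new.t();
      cfg_of(j) = cfg_new;
      for (int s = 0; s < t; ++s) D(j, s) = (cfg_new >> s) & 1;
    }

    // covariance / inclusion-rate updates
    if (diagonal_cov) {
      for (int s = 0; s < t; ++s) {
        double ssb = 0.0; int m1 = 0;
        for (int j = 0; j < m; ++j)
          if (D(j, s)) { ssb += B(j, s) * B(j, s); ++m1; }
        if (est_VB) VB(s, s) = rinvchisq(nub_diag, Sb_diag(s), ssb, (double)m1);
        if (est_VE)
          VE(s, s) = rinvchisq(nue_diag, Se_diag(s),
                               arma::dot(Rres.col(s), Rres.col(s)), (double)n);
      }
    } else {
      if (est_VB) {
        arma::mat S = S_B;
        int n_incl = 0;
        for (int j = 0; j < m; ++j) {
          if (cfg_of(j) != 0) {
            S += B.row(j).t() * B.row(j);
            ++n_incl;
          }
        }
        VB = riwish(S, nu_B + n_incl);
      }
      if (est_VE) VE = riwish(S_E + Rres.t() * Rres, nu_E + n);
    }
    if (estimate_pi) {
      if (combination) {
        arma::vec counts(ncfg, arma::fill::ones);   // Dirichlet alpha = 1
        for (int j = 0; j < m; ++j) counts(cfg_of(j)) += 1.0;
        for (int cfg = 0; cfg < ncfg; ++cfg)
          pcfg(cfg) = R::rgamma(counts(cfg), 1.0);
        pcfg /= arma::accu(pcfg);
      } else {
        for (int s = 0; s < t; ++s) {
          int m1 = arma::accu(D.col(s));
          pi_t(s) = R::rbeta(m1 + 1.0, m - m1 + 1.0);
        }
      }
    }

    if (it >= burn_in) {
      const int k = it - burn_in;
      for (int j = 0; j < m; ++j) {
        bool any = false;
        for (int s = 0; s < t; ++s) {
          pip(j, s) += D(j, s);
          Bsum(j, s) += B(j, s);
          if (D(j, s)) any = true;
        }
        if (any) pip_any(j) += 1.0;
      }
      VBsum += VB; VEsum += VE;
      VBd_s.row(k) = VB.diag().t();
      VEd_s.row(k) = VE.diag().t();
      if (keep_samples) B_keep.row(k) = arma::vectorise(B).t();
    }
  }
  pip /= n_keep; Bsum /= n_keep; pip_any /= n_keep;
  VBsum /= n_keep; VEsum /= n_keep;
  List out = List::create(
    Named("pip") = pip, Named("pip_any") = pip_any, Named("B_mean") = Bsum,
    Named("V_B_mean") = VBsum, Named("V_E_mean") = VEsum,
    Named("samples_VB_diag") = VBd_s, Named("samples_VE_diag") = VEd_s);
  out["B_samples"] = keep_samples ? wrap(B_keep) : R_NilValue;
  return out;
}
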