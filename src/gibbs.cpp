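// Core numerical routines for the continuous-shrinkage Gibbs sampler.
//
// The model (standardized genotypes Z, standardized phenotype y):
//   y = Z beta + e,   e ~ N(0, sigma2 I),   p(sigma2) propto 1/sigma2
//   beta_j ~ N(0, sigma2/N * phi * psi_j)
//   psi_j ~ Gamma(a, rate delta_j),  delta_j ~ Gamma(b, rate 1)
// Inference uses only bhat = Z'y/N and per-block LD matrices D = Z'Z/N.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include "gig.h"

using namespace Rcpp;

static bool chol_lower_jitter(arma::mat& L, const arma::mat& A, double& jitter_used) {
  if (arma::chol(L, A, "lower")) { jitter_used = 0.0; return true; }
  static const double ladder[3] = {1e-10, 1e-8, 1e-6};
  for (int k = 0; k < 3; ++k) {
    arma::mat Aj = A;
    Aj.diag() += ladder[k];
    if (arma::chol(L, Aj, "lower")) { jitter_used = ladder[k]; return true; }
  }
  return false;
}

// Draw ndraws samples of beta for one LD block, conditioning on the current
// local scales. T_jj = min(phi * psi_j, 1/rho) implements the regularization
// floor phi^{-1} psi_j^{-1} >= rho. Returns an m x ndraws matrix.
// [[Rcpp::export(name = ".cppUpdateBetaBlock")]]
arma::mat cpp_update_beta_block(const arma::mat& D, const arma::vec& bhat,
                                const arma::vec& psi, double phi,
                                double sigma2, double n_eff, double rho,
                                int ndraws) {
  const int m = D.n_rows;
  arma::mat A = D;
  for (int j = 0; j < m; ++j) {
    double t = phi * psi[j];
    if (rho > 0.0 && t > 1.0 / rho) t = 1.0 / rho;
    A(j, j) += 1.0 / t;
  }
  arma::mat L;
  double jit = 0.0;
  if (!chol_lower_jitter(L, A, jit))
    stop("block update: Cholesky factorization failed after jitter ladder (m = %d)", m);
  // draw as L^-T (L^-1 bhat + sd z): one forward solve shared by all draws
  const arma::mat Lt = L.t();
  const arma::vec v = arma::solve(arma::trimatl(L), bhat);
  const double sd = std::sqrt(sigma2 / n_eff);
  arma::mat out(m, ndraws);
  arma::vec z(m);
  for (int d = 0; d < ndraws; ++d) {
    for (int j = 0; j < m; ++j) z[j] = v[j] + sd * norm_rand();
    out.col(d) = arma::solve(arma::trimatu(Lt), z);
  }
  return out;
}

// Vectorized GIG draws, one per (chi, psi) pair.
// [[Rcpp::export(name = ".cppSampleGIG")]]
NumericVector cpp_sample_gig(int n, double p, const NumericVector& chi,
                             const NumericVector& psi) {
  NumericVector out(n);
  const int nc = chi.size(), np = psi.size();
  for (int i = 0; i < n; ++i)
    out[i] = csprs::rgig(p, chi[i % nc], psi[i % np]);
  return out;
}

// Full MCMC loop. Dlist/bhatlist hold per-block LD matrices and standardized
// marginal effects; returns post-burn-in posterior means and a trace.
// [[Rcpp::export(name = ".cppRunGibbs")]]
List cpp_run_gibbs(const List& Dlist, const List& bhatlist,
                   double a, double b, double phi_init, bool phi_auto,
                   double n_eff, int n_iter, int n_burnin, int thin,
                   double rho, bool keep_trace) {
  const int nblk = Dlist.size();
  std::vector<arma::mat> D(nblk);
  std::vector<arma::vec> bhat(nblk);
  std::vector<arma::uvec> offs(nblk);
  int M = 0;
  for (int k = 0; k < nblk; ++k) {
    D[k] = as<arma::mat>(Dlist[k]);
    bhat[k] = as<arma::vec>(bhatlist[k]);
    M += bhat[k].n_elem;
  }

  arma::vec beta(M, arma::fill::zeros);
  arma::vec psi(M, arma::fill::ones);
  arma::vec delta(M, arma::fill::ones);
  double sigma2 = 1.0, phi = phi_auto ? 1.0 : phi_init, w = 1.0;

  arma::vec beta_sum(M, arma::fill::zeros);
  double phi_sum = 0.0, sigma2_sum = 0.0;
  int n_save = 0;

  const int ncol_tr = keep_trace ? 4 : 0;
  arma::mat trace(keep_trace ? n_iter : 0, ncol_tr);

  for (int it = 0; it < n_iter; ++it) {
    // beta: blockwise multivariate-normal updates in genomic order
    int off = 0;
    double bDb = 0.0, bbhat = 0.0;
    for (int k = 0; k < nblk; ++k) {
      const int m = bhat[k].n_elem;
      if (m == 0) continue;
      arma::vec bk = cpp_update_beta_block(D[k], bhat[k],
                                           psi.subvec(off, off + m - 1),
                                           phi, sigma2, n_eff, rho, 1);
      beta.subvec(off, off + m - 1) = bk;
      bDb += arma::as_scalar(bk.t() * D[k] * bk);
      bbhat += arma::dot(bk, bhat[k]);
      off += m;
    }

    // local scales: psi_j | . ~ GIG(a - 1/2, N b_j^2/(sigma2 phi), 2 delta_j)
    // delta_j | psi_j ~ Gamma(a + b, rate psi_j + 1)
    for (int j = 0; j < M; ++j) {
      const double chi = n_eff * beta[j] * beta[j] / (sigma2 * phi);
      psi[j] = csprs::rgig(a - 0.5, chi, 2.0 * delta[j]);
      delta[j] = R::rgamma(a + b, 1.0 / (psi[j] + 1.0));
    }

    // residual variance: InvGamma((N+M)/2, N/2 [quad + sum beta^2/(phi psi)])
    double quad = 1.0 - 2.0 * bbhat + bDb;
    if (quad < 1e-6) quad = 1e-6;
    double prior_ss = 0.0;
    for (int j = 0; j < M; ++j) prior_ss += beta[j] * beta[j] / (phi * psi[j]);
    const double shape_s = 0.5 * (n_eff + M);
    const double rate_s = 0.5 * n_eff * (quad + prior_ss);
    sigma2 = rate_s / R::rgamma(shape_s, 1.0);

    // global scale (auto mode): half-Cauchy on phi^{1/2} via the
    // inverse-gamma auxiliary w
    if (phi_auto) {
      w = (1.0 + 1.0 / phi) / R::rgamma(1.0, 1.0);
      double sbp = 0.0;
      for (int j = 0; j < M; ++j) sbp += beta[j] * beta[j] / psi[j];
      const double rate_p = 1.0 / w + 0.5 * n_eff * sbp / sigma2;
      phi = rate_p / R::rgamma(0.5 * (M + 1), 1.0);
      if (!std::isfinite(phi) || phi <= 0.0)
        stop("auto update of the global scale produced a non-finite value at iteration %d", it + 1);
    }

    if (keep_trace) {
      trace(it, 0) = it + 1;
      trace(it, 1) = sigma2;
      trace(it, 2) = phi;
      trace(it, 3) = arma::mean(arma::abs(beta));
    }

    if (it >= n_burnin && ((it - n_burnin) % thin == 0)) {
      beta_sum += beta;
      phi_sum += phi;
      sigma2_sum += sigma2;
      ++n_save;
    }
  }

  return List::create(
    _["beta_mean"] = beta_sum / n_save,
    _["phi_mean"] = phi_sum / n_save,
    _["sigma2_mean"] = sigma2_sum / n_save,
    _["n_save"] = n_save,
    _["trace"] = trace);
}
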