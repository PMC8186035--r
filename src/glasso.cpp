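#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double soft(double x, double l) {
  if (x > l) return x - l;
  if (x < -l) return x + l;
  return 0.0;
}

// Graphical lasso by block coordinate descent (Friedman, Hastie & Tibshirani
// 2008): cycle over columns of the covariance estimate W, solving each
// column's lasso subproblem by coordinate descent. W and B allow warm starts
// along a regularization path.
// [[Rcpp::export]]
List glasso_cpp(const arma::mat& S, double lambda, arma::mat W, arma::mat B,
                double tol, int maxit, int inner_maxit) {
  const int p = S.n_rows;
  double offsum = arma::accu(arma::abs(S)) - arma::accu(arma::abs(S.diag()));
  double thr = tol * std::max(offsum / std::max(p * (p - 1), 1), 1e-12);
  bool converged = false;

  std::vector<arma::uvec> others(p);
  for (int j = 0; j < p; ++j) {
    arma::uvec idx(p - 1);
    int c = 0;
    for (int k = 0; k < p; ++k) if (k != j) idx(c++) = k;
    others[j] = idx;
  }

  for (int it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (int j = 0; j < p; ++j) {
      const arma::uvec& idx = others[j];
      arma::mat W11 = W(idx, idx);
      arma::vec s12 = S.col(j);
      s12 = s12(idx);
      arma::vec beta = B.col(j);
      beta = beta(idx);
      for (int ii = 0; ii < inner_maxit; ++ii) {
        double d = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double old = beta(k);
          double g = s12(k) - arma::dot(W11.col(k), beta) + W11(k, k) * old;
          double nb = soft(g, lambda) / W11(k, k);
          if (nb != old) {
            beta(k) = nb;
            double ad = std::fabs(nb - old);
            if (ad > d) d = ad;
          }
        }
        if (d < thr * 0.1) break;
      }
      arma::vec w12 = W11 * beta;
      for (int k = 0; k < p - 1; ++k) {
        double dd = std::fabs(W(idx(k), j) - w12(k));
        if (dd > maxdiff) maxdiff = dd;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        B(idx(k), j) = beta(k);
      }
    }
    if (maxdiff < thr) { converged = true; break; }
  }

  // back out the precision matrix from the final W and lasso coefficients
  arma::mat Theta(p, p, arma::fill::zeros);
  for (int j = 0; j < p; ++j) {
    const arma::uvec& idx = others[j];
    arma::vec beta = B.col(j);
    beta = beta(idx);
    arma::vec w12 = W.col(j);
    w12 = w12(idx);
    double t22 = 1.0 / (W(j, j) - arma::dot(w12, beta));
    Theta(j, j) = t22;
    for (int k = 0; k < p - 1; ++k) Theta(idx(k), j) = -beta(k) * t22;
  }
  Theta = 0.5 * (Theta + Theta.t());
  return List::create(_["W"] = W, _["Theta"] = Theta, _["B"] = B,
                      _["converged"] = converged);
}
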