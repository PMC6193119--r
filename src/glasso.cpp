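// L1-penalised Gaussian precision estimation (graphical lasso),
// block coordinate descent over columns of the working covariance W
// (Friedman-style), with the penalty applied to off-diagonal entries only,
// so diag(W) == diag(S) throughout and the full-shrinkage limit is
// theta = diag(1/diag(S)).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Coordinate-descent lasso for: min 0.5 b' W11 b - s12' b + lambda ||b||_1
static void lasso_cd(const mat& W11, const vec& s12, double lambda, vec& beta,
                     int maxit, double tol) {
  const uword m = s12.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double delta = 0.0;
    for (uword k = 0; k < m; ++k) {
      double old = beta(k);
      // residual gradient excluding coordinate k
      double r = s12(k) - dot(W11.col(k), beta) + W11(k, k) * old;
      double bk = soft(r, lambda) / W11(k, k);
      beta(k) = bk;
      delta = std::max(delta, std::fabs(bk - old));
    }
    if (delta < tol) break;
  }
}

// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda,
                      int maxit = 200, double tol = 1e-7) {
  const uword p = S.n_rows;
  mat W = S;                 // working covariance estimate, diag fixed at diag(S)
  mat Beta(p, p, fill::zeros); // column j holds beta for column j (p-1 used)

  bool converged = (p == 1);
  int iter = 0;
  const double scale = std::max(mean(abs(vectorise(S))), 1e-12);

  if (p > 1) {
    for (iter = 1; iter <= maxit; ++iter) {
      double shift = 0.0;
      for (uword j = 0; j < p; ++j) {
        uvec idx(p - 1);
        uword c = 0;
        for (uword i = 0; i < p; ++i) if (i != j) idx(c++) = i;
        mat W11 = W(idx, idx);
        vec s12 = S.col(j);
        s12 = s12(idx);
        vec beta = Beta.col(j);
        beta = beta(idx);
        lasso_cd(W11, s12, lambda, beta, 200, tol * scale * 0.1);
        vec w12 = W11 * beta;
        for (uword k = 0; k < p - 1; ++k) {
          shift = std::max(shift, std::fabs(W(idx(k), j) - w12(k)));
          W(idx(k), j) = w12(k);
          W(j, idx(k)) = w12(k);
          Beta(idx(k), j) = beta(k);
        }
      }
      if (shift < tol * scale) { converged = true; break; }
    }
  }

  // recover the precision matrix from W and the column solutions
  mat Theta(p, p, fill::zeros);
  if (p == 1) {
    Theta(0, 0) = 1.0 / S(0, 0);
  } else {
    for (uword j = 0; j < p; ++j) {
      uvec idx(p - 1);
      uword c = 0;
      for (uword i = 0; i < p; ++i) if (i != j) idx(c++) = i;
      vec beta = Beta.col(j);
      beta = beta(idx);
      vec w12 = W.col(j);
      w12 = w12(idx);
      double theta_jj = 1.0 / (W(j, j) - dot(w12, beta));
      Theta(j, j) = theta_jj;
      for (uword k = 0; k < p - 1; ++k)
        Theta(idx(k), j) = -beta(k) * theta_jj;
    }
    Theta = 0.5 * (Theta + Theta.t());
  }

  double sign = 0.0, ldet = 0.0;
  log_det(ldet, sign, Theta);
  double pen = lambda * (accu(abs(Theta)) - trace(abs(Theta)));
  double obj = (sign > 0.0) ? (ldet - trace(S * Theta) - pen) : R_NegInf;

  return Rcpp::List::create(
    Rcpp::Named("theta") = Theta,
    Rcpp::Named("w") = W,
    Rcpp::Named("objective") = obj,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = iter);
}
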