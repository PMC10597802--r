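// L1-penalised inverse covariance (graphical lasso) by blockwise coordinate
// descent (lasso subproblem per column, warm-started across sweeps). At
// lambda = 0 the estimate is the plain inverse of the (SPD) covariance.
// glasso_windows_cpp fits a whole sequence of window covariances at one
// penalty, warm-starting each fit from the previous window's solution
// (neighbouring sliding windows share all but one sample, so their solutions
// are close); the warm start changes iteration counts only, not solutions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat glasso_core(const mat& S, double lambda, int max_iter, double tol,
                       mat& B) {
  const int p = S.n_rows;
  if (lambda <= 0.0) {
    return inv_sympd(S);
  }
  mat W = S;
  W.diag() += lambda;

  double off_mean = 0.0;
  int n_off = 0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) { off_mean += std::abs(S(i, j)); ++n_off; }
  off_mean = n_off > 0 ? off_mean / n_off : 1.0;
  double thr = tol * std::max(off_mean, 1e-12);

  uvec all = regspace<uvec>(0, p - 1);
  std::vector<uvec> idx(p);
  for (int j = 0; j < p; ++j) idx[j] = find(all != (unsigned) j);

  for (int it = 0; it < max_iter; ++it) {
    double max_change = 0.0;
    for (int j = 0; j < p; ++j) {
      mat W11 = W.submat(idx[j], idx[j]);
      vec s12 = S.col(j);
      vec s12r = s12.elem(idx[j]);
      vec beta = B.col(j);
      for (int cd = 0; cd < 200; ++cd) {
        double cd_change = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double old = beta(k);
          double x = s12r(k) - dot(W11.col(k), beta) + W11(k, k) * old;
          double b = 0.0;
          if (x > lambda) b = (x - lambda) / W11(k, k);
          else if (x < -lambda) b = (x + lambda) / W11(k, k);
          beta(k) = b;
          cd_change = std::max(cd_change, std::abs(b - old));
        }
        if (cd_change < 0.1 * thr) break;
      }
      B.col(j) = beta;
      vec w12 = W11 * beta;
      uvec jj(1); jj(0) = j;
      vec w_old = W.submat(idx[j], jj);
      double ch = abs(w_old - w12).max();
      max_change = std::max(max_change, ch);
      W.submat(idx[j], jj) = w12;
      W.submat(jj, idx[j]) = w12.t();
    }
    if (max_change < thr) break;
  }

  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    uvec jj(1); jj(0) = j;
    vec beta = B.col(j);
    vec w12 = W.submat(idx[j], jj);
    double tjj = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = tjj;
    vec t12 = -beta * tjj;
    Theta.submat(idx[j], jj) = t12;
  }
  return 0.5 * (Theta + Theta.t());
}

// [[Rcpp::export]]
arma::mat glasso_fit_cpp(const arma::mat& S_in, double lambda,
                         int max_iter = 100, double tol = 1e-6) {
  mat S = symmatu(S_in);
  mat B(S.n_rows > 0 ? S.n_rows - 1 : 0, S.n_rows, fill::zeros);
  return glasso_core(S, lambda, max_iter, tol, B);
}

// [[Rcpp::export]]
arma::cube glasso_windows_cpp(const arma::cube& S_seq, double lambda,
                              int max_iter = 100, double tol = 1e-6) {
  const int p = S_seq.n_rows;
  const int W = S_seq.n_slices;
  cube out(p, p, W);
  mat B(p > 0 ? p - 1 : 0, p, fill::zeros);
  for (int w = 0; w < W; ++w) {
    mat S = symmatu(S_seq.slice(w));
    out.slice(w) = glasso_core(S, lambda, max_iter, tol, B);
  }
  return out;
}
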