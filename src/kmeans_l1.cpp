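// k-means under the Manhattan (L1, city-block) distance: assignment by
// minimum L1 distance, centroid update by coordinate-wise median (the exact
// L1 minimiser). Initial centroid indices are drawn in R so reproducibility
// follows R's RNG. Empty clusters are re-seeded at the sample farthest from
// its assigned centroid. Data are held transposed (features x samples) so
// inner loops walk contiguous memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List kmeans_l1_cpp(const arma::mat& X, int k,
                         const arma::umat& init_idx, int max_iter = 150) {
  const int n = X.n_rows;
  const int d = X.n_cols;
  const int n_rep = init_idx.n_rows;
  const mat Xt = X.t();            // d x n, column per sample

  double best_obj = datum::inf;
  uvec best_assign;
  mat best_C;
  std::vector<double> best_trace;
  int best_iters = 0;
  int n_reseeds = 0;

  for (int r = 0; r < n_rep; ++r) {
    mat Ct(d, k);                  // d x k, column per centroid
    for (int c = 0; c < k; ++c) Ct.col(c) = Xt.col(init_idx(r, c));
    uvec assign(n, fill::zeros);
    uvec prev(n);
    prev.fill(n + 1);
    std::vector<double> trace;
    int it = 0;
    double obj = 0.0;

    for (it = 0; it < max_iter; ++it) {
      vec mind(n);
      obj = 0.0;
      for (int i = 0; i < n; ++i) {
        const double* xi = Xt.colptr(i);
        double dmin = datum::inf;
        int amin = 0;
        for (int c = 0; c < k; ++c) {
          const double* cc = Ct.colptr(c);
          double dist = 0.0;
          for (int j = 0; j < d; ++j) dist += std::abs(xi[j] - cc[j]);
          if (dist < dmin) { dmin = dist; amin = c; }
        }
        assign(i) = amin;
        mind(i) = dmin;
        obj += dmin;
      }
      for (int c = 0; c < k; ++c) {
        if (!any(assign == (unsigned) c)) {
          uword far = mind.index_max();
          assign(far) = c;
          Ct.col(c) = Xt.col(far);
          mind(far) = 0.0;
          ++n_reseeds;
        }
      }
      trace.push_back(obj);
      if (all(assign == prev)) break;
      prev = assign;
      for (int c = 0; c < k; ++c) {
        uvec members = find(assign == (unsigned) c);
        if (members.n_elem > 0) {
          Ct.col(c) = median(Xt.cols(members), 1);
        }
      }
    }
    obj = 0.0;
    for (int i = 0; i < n; ++i) {
      const double* xi = Xt.colptr(i);
      double dmin = datum::inf;
      for (int c = 0; c < k; ++c) {
        const double* cc = Ct.colptr(c);
        double dist = 0.0;
        for (int j = 0; j < d; ++j) dist += std::abs(xi[j] - cc[j]);
        dmin = std::min(dmin, dist);
      }
      obj += dmin;
    }
    if (obj < best_obj) {
      best_obj = obj;
      best_assign = assign;
      best_C = Ct.t();
      best_trace = trace;
      best_iters = it + 1;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("assignments") = Rcpp::IntegerVector(
        best_assign.begin(), best_assign.end()),
    Rcpp::Named("centroids") = best_C,
    Rcpp::Named("objective") = best_obj,
    Rcpp::Named("trace") = best_trace,
    Rcpp::Named("iterations") = best_iters,
    Rcpp::Named("reseeds") = n_reseeds);
}

// [[Rcpp::export]]
arma::mat l1_cross_dist_cpp(const arma::mat& X, const arma::mat& C) {
  const mat Xt = X.t();
  const mat Ct = C.t();
  mat D(X.n_rows, C.n_rows);
  for (uword i = 0; i < X.n_rows; ++i) {
    const double* xi = Xt.colptr(i);
    for (uword c = 0; c < C.n_rows; ++c) {
      const double* cc = Ct.colptr(c);
      double dist = 0.0;
      for (uword j = 0; j < Xt.n_rows; ++j) dist += std::abs(xi[j] - cc[j]);
      D(i, c) = dist;
    }
  }
  return D;
}
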