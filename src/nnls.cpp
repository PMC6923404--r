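#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set non-negative least squares:
// minimise ||A x - b||^2 subject to x >= 0.
static vec nnls_lh(const mat& A, const vec& b, double tol) {
  const uword p = A.n_cols;
  vec x(p, fill::zeros);
  std::vector<bool> passive(p, false);
  vec w = A.t() * (b - A * x);
  uword iter = 0, max_iter = 30 * p;
  while (iter++ < max_iter) {
    // pick most violated zero coordinate
    int t = -1;
    double wmax = tol;
    for (uword j = 0; j < p; ++j)
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = (int)j; }
    if (t < 0) break;
    passive[t] = true;
    for (;;) {
      uvec P(p); uword np = 0;
      for (uword j = 0; j < p; ++j) if (passive[j]) P(np++) = j;
      P.resize(np);
      vec z;
      bool ok = solve(z, A.cols(P), b);
      if (!ok) { passive[t] = false; return x; }
      if (z.min() > 0) {
        x.zeros();
        for (uword k = 0; k < np; ++k) x(P(k)) = z(k);
        break;
      }
      // step back to the boundary
      double alpha = datum::inf;
      for (uword k = 0; k < np; ++k)
        if (z(k) <= 0) {
          double a = x(P(k)) / (x(P(k)) - z(k));
          if (a < alpha) alpha = a;
        }
      for (uword k = 0; k < np; ++k)
        x(P(k)) += alpha * (z(k) - x(P(k)));
      for (uword k = 0; k < np; ++k)
        if (x(P(k)) <= tol) { passive[P(k)] = false; x(P(k)) = 0; }
    }
    w = A.t() * (b - A * x);
  }
  return x;
}

// [[Rcpp::export]]
arma::vec nnls_solve(const arma::mat& A, const arma::vec& b) {
  return nnls_lh(A, b, 1e-10);
}

// Compensate observed = true %*% S for spillover: per event (row y of Y)
// solve min ||x S - y||^2, x >= 0, i.e. NNLS with A = S^T.  Events whose
// unconstrained solution y S^{-1} is already non-negative take the fast
// path (a single matrix multiply for the whole table).
// [[Rcpp::export]]
arma::mat compensate_counts(const arma::mat& Y, const arma::mat& S) {
  mat Sinv;
  if (!inv(Sinv, S))
    Rcpp::stop("spillover matrix is singular");
  mat X = Y * Sinv;
  mat A = S.t();
  const double tol = -1e-9;
  for (uword i = 0; i < X.n_rows; ++i) {
    if (X.row(i).min() < tol) {
      X.row(i) = nnls_lh(A, Y.row(i).t(), 1e-10).t();
    } else {
      for (uword j = 0; j < X.n_cols; ++j)
        if (X(i, j) < 0) X(i, j) = 0;  // clamp float dust
    }
  }
  return X;
}
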