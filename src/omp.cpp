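#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Batch orthogonal matching pursuit.
//
// D: K x A dictionary with unit-norm atoms; X: K x P signal columns;
// t0: maximum atoms per column; eps: per-column absolute residual
// tolerance (stop early once ||r||_2 <= eps).
//
// Greedy rule: pick the atom with the largest absolute correlation with
// the current residual (first index on exact ties, already-selected atoms
// excluded), then least-squares refit on the selected support.
// [[Rcpp::export]]
arma::mat omp_encode_cpp(const arma::mat& D, const arma::mat& X,
                         const int t0, const arma::vec& eps) {
  const uword A = D.n_cols, P = X.n_cols;
  if (D.n_rows != X.n_rows) Rcpp::stop("dimension mismatch between D and X");
  if (eps.n_elem != P) Rcpp::stop("eps must have one entry per column");
  mat codes(A, P, fill::zeros);
  uvec support(t0);
  for (uword p = 0; p < P; ++p) {
    const vec x = X.col(p);
    const double tol = eps(p);
    if (norm(x, 2) <= tol) continue;
    vec r = x;
    vec coef;
    int s = 0;
    while (s < t0) {
      vec c = abs(D.t() * r);
      for (int q = 0; q < s; ++q) c(support(q)) = -1.0;
      support(s++) = c.index_max();
      const mat Ds = D.cols(support.head(s));
      coef = solve(Ds.t() * Ds, Ds.t() * x, solve_opts::fast);
      r = x - Ds * coef;
      if (norm(r, 2) <= tol) break;
    }
    for (int q = 0; q < s; ++q) codes(support(q), p) = coef(q);
  }
  return codes;
}
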