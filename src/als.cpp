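// Alternating least squares engine for rectangular matrices with missing
// cells.  Row solves use only the observed columns of each row, column solves
// only the observed rows of each column; R is re-orthonormalized by QR after
// every row half-iteration.  Anchors: the leading `n_anchor_dims` columns of
// R and any column index in `anchor_cols` (0-based) are held fixed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Least-squares solve of A * b ~= y with minimum-norm fallback for
// rank-deficient systems (no ridge penalty anywhere).
static vec ls_solve(const mat& A, const vec& y) {
  vec b;
  bool ok = solve(b, A, y, solve_opts::no_approx);
  if (!ok) b = pinv(A) * y;
  return b;
}

// [[Rcpp::export(name = ".als_engine")]]
Rcpp::List als_engine(const arma::mat& X,
                      arma::mat R,
                      arma::mat C,
                      int n_anchor_dims,
                      const arma::uvec& anchor_cols,
                      double tol,
                      int max_iter,
                      bool orthonormalize) {
  const uword N = X.n_rows, I = X.n_cols;
  const uword d = C.n_rows;
  const uword k = (uword) n_anchor_dims;

  // observed-cell index cache
  std::vector<uvec> row_obs(N), col_obs(I);
  for (uword n = 0; n < N; ++n) row_obs[n] = find_finite(X.row(n).t());
  for (uword i = 0; i < I; ++i) col_obs[i] = find_finite(X.col(i));

  std::vector<bool> col_anchored(I, false);
  for (uword j = 0; j < anchor_cols.n_elem; ++j) col_anchored[anchor_cols(j)] = true;

  // flattened observed values for convergence tracking
  uword n_obs = 0;
  for (uword i = 0; i < I; ++i) n_obs += col_obs[i].n_elem;
  vec e_prev(n_obs, fill::zeros), e_cur(n_obs);
  std::vector<double> rms_resid;

  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    // --- row half-iteration: R_n from C over observed cells
    for (uword n = 0; n < N; ++n) {
      const uvec& o = row_obs[n];
      if (o.n_elem == 0) continue;
      vec xr = X.row(n).t();
      vec y = xr.elem(o);
      if (k > 0) {
        mat Ca = C.rows(0, k - 1);
        y -= (R.row(n).cols(0, k - 1) * Ca.cols(o)).t();
        if (k < d) {
          mat Cf = C.rows(k, d - 1);
          mat A = Cf.cols(o).t();           // m x (d-k)
          R.row(n).cols(k, d - 1) = ls_solve(A, y).t();
        }
      } else {
        mat A = C.cols(o).t();              // m x d
        R.row(n) = ls_solve(A, y).t();
      }
    }

    // --- orthonormalize the free block of R (QR, deterministic sign)
    if (orthonormalize && k < d) {
      mat Rf = R.cols(k, d - 1);
      if (k > 0) {
        mat Ra = R.cols(0, k - 1);
        Rf -= Ra * (Ra.t() * Rf);           // keep free block orthogonal to anchors
      }
      mat Q, T;
      qr_econ(Q, T, Rf);
      for (uword j = 0; j < Q.n_cols; ++j)
        if (T(j, j) < 0) Q.col(j) *= -1.0;
      R.cols(k, d - 1) = Q;
    }

    // --- column half-iteration: C_i from R over observed cells
    for (uword i = 0; i < I; ++i) {
      if (col_anchored[i]) continue;
      const uvec& o = col_obs[i];
      if (o.n_elem == 0) continue;
      mat B = R.rows(o);                    // m x d
      vec xc = X.col(i);
      C.col(i) = ls_solve(B, xc.elem(o));
    }

    // --- convergence: RMS change of E over observed cells
    uword pos = 0;
    double ss_res = 0.0;
    for (uword i = 0; i < I; ++i) {
      const uvec& o = col_obs[i];
      if (o.n_elem == 0) continue;
      vec e = R.rows(o) * C.col(i);
      vec xc = X.col(i);
      vec y = xc.elem(o);
      ss_res += accu(square(y - e));
      e_cur.subvec(pos, pos + o.n_elem - 1) = e;
      pos += o.n_elem;
    }
    rms_resid.push_back(std::sqrt(ss_res / (double) n_obs));
    double rms_change = std::sqrt(accu(square(e_cur - e_prev)) / (double) n_obs);
    e_prev = e_cur;
    if (iter > 1 && rms_change < tol) { converged = true; break; }
  }

  return Rcpp::List::create(
    Rcpp::Named("R") = R,
    Rcpp::Named("C") = C,
    Rcpp::Named("n_iter") = std::min(iter, max_iter),
    Rcpp::Named("converged") = converged,
    Rcpp::Named("rms_resid") = rms_resid);
}
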