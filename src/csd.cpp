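// Inner loop of the constrained spherical deconvolution fit.
// One voxel at a time: iteratively reweighted Tikhonov solve where the
// penalty selects constraint-tessellation rows whose current fODF amplitude
// is below the threshold. The penalty Gram matrix is formed by subtracting
// the (small) unconstrained-row contribution from the full Gram matrix.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
arma::mat csd_fit_batch_cpp(const arma::mat& S, const arma::mat& F,
                            const arma::mat& Bc, const arma::mat& Ainit,
                            double lambda, double tau, int max_iter) {
  const uword nc = F.n_cols, nv = S.n_cols;
  const mat FtF = F.t() * F;
  const mat BtB = Bc.t() * Bc;
  const mat Ft = F.t();
  const double l2 = lambda * lambda;
  mat out(nc, nv, fill::zeros);

  for (uword v = 0; v < nv; ++v) {
    vec rhs = Ft * S.col(v);
    vec a = Ainit.col(v);
    vec amp = Bc * a;
    const double thr = tau * mean(amp);
    uvec prev;
    bool have_prev = false;
    for (int it = 0; it < max_iter; ++it) {
      uvec excl = find(amp >= thr);  // rows NOT penalized
      mat M = FtF + l2 * BtB;
      if (excl.n_elem > 0) {
        mat Be = Bc.rows(excl);
        M -= l2 * (Be.t() * Be);
      }
      bool ok = solve(a, M, rhs, solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok) {
        a = solve(M + 1e-10 * eye(nc, nc), rhs);
      }
      amp = Bc * a;
      uvec cur = find(amp < thr);
      if (have_prev && cur.n_elem == prev.n_elem &&
          (cur.n_elem == 0 || all(cur == prev)))
        break;
      prev = cur;
      have_prev = true;
    }
    out.col(v) = a;
  }
  return out;
}
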