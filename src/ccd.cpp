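// Cyclic coordinate descent for the Frobenius-regularized NMF
//   min_{W,H >= 0} ||WH - V||_F^2 + (lambda/2)(||W||_F^2 + ||H||_F^2)
// One sweep updates every entry of W (row-major over rows, coordinates
// t = 1..k) then every entry of H (column-major), each by the exact
// non-negative minimizer of its one-variable subproblem. Gram matrices
// H H^T / W^T W and the sparse products V H^T / V^T W are cached, so a
// sweep costs O(nnz(V) k + (m + n) k^2) without forming a dense residual.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// z* = max(0, (p - sum_{t'} w_{it'} G_{t't} + w_{it} G_{tt}) / (G_{tt} + lambda/2))
// where p = (V H^T)_{it}, G = H H^T; symmetric rule for H.
static void update_factor_rows(mat& W, const mat& G, const mat& P,
                               const double lambda) {
  const uword m = W.n_rows, k = W.n_cols;
  for (uword i = 0; i < m; ++i) {
    for (uword t = 0; t < k; ++t) {
      double denom = G(t, t) + lambda / 2.0;
      if (denom <= 0.0) { W(i, t) = 0.0; continue; }
      double num = P(i, t) - dot(W.row(i), G.col(t)) + W(i, t) * G(t, t);
      W(i, t) = num > 0.0 ? num / denom : 0.0;
    }
  }
}

// [[Rcpp::export(name = ".ccd_fit_cpp")]]
Rcpp::List ccd_fit_cpp(const arma::sp_mat& V, arma::mat W, arma::mat H,
                       const double lambda, const int max_sweeps,
                       const double rel_tol) {
  const double vnorm2 = accu(square(nonzeros(V)));
  std::vector<double> trace;
  trace.reserve(max_sweeps);
  bool converged = false;
  double f_prev = datum::inf;

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    mat G = H * H.t();              // k x k
    mat P = mat(V * H.t());         // m x k, O(nnz k)
    update_factor_rows(W, G, P, lambda);

    mat Gw = W.t() * W;             // k x k
    mat Q = mat(V.t() * W);         // n x k
    // H update: column-major over cells; reuse row-update kernel on H^T.
    mat Ht = H.t();                 // n x k
    update_factor_rows(Ht, Gw, Q, lambda);
    H = Ht.t();

    // f(W,H) via Gram identities: ||WH-V||^2 = tr(W'W H H') - 2<WH,V> + ||V||^2
    mat GwNew = W.t() * W;
    mat GhNew = H * H.t();
    double cross = accu(mat(V.t() * W) % H.t());
    double rss = accu(GwNew % GhNew) - 2.0 * cross + vnorm2;
    double f = rss + 0.5 * lambda * (accu(square(W)) + accu(square(H)));
    if (!std::isfinite(f))
      Rcpp::stop("non-finite objective at sweep %d", sweep + 1);
    trace.push_back(f);
    if (std::isfinite(f_prev) && f_prev > 0.0 &&
        std::fabs(f_prev - f) / f_prev < rel_tol) {
      converged = true;
      break;
    }
    f_prev = f;
  }

  // final RSS (fit error only, regularization excluded)
  double cross = accu(mat(V.t() * W) % H.t());
  double rss = accu((W.t() * W) % (H * H.t())) - 2.0 * cross + vnorm2;

  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("H") = H,
                            Rcpp::Named("objective") = trace,
                            Rcpp::Named("rss") = rss,
                            Rcpp::Named("converged") = converged);
}
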