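// Batch lag-1 VAR fits over many node subsets of one participant's panel.
//
// Semantics mirror fit_var()/contemporaneous_from_residuals() exactly:
// per-equation listwise deletion (row used when the outcome and all k lagged
// predictors are observed), intercept always estimated, no penalization;
// contemporaneous edges from the residual covariance on the rows common to
// all k equations. R-level tests assert equality with the pure-R path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// OLS coefficients for D * b = y via normal equations; false when singular
bool ols(const mat& D, const vec& y, vec& beta) {
  mat A = D.t() * D;
  vec b = D.t() * y;
  return solve(beta, A, b, solve_opts::no_approx + solve_opts::likely_sympd);
}

} // namespace

// X: (T-1) x p lagged values, Y: (T-1) x p outcomes (NaN = missing)
// subsets: k x m matrix of 1-based column indices
// type: 0 = directed, 1 = contemporaneous partial, 2 = contemporaneous
//       zero-order
// want_edges: also return the vectorized edge matrix per subset
// fail codes: 0 ok, 1 insufficient rows, 2 singular/collinear
// [[Rcpp::export]]
Rcpp::List batch_fit_cpp(const arma::mat& X, const arma::mat& Y,
                         const arma::imat& subsets, int type,
                         bool want_edges) {
  const uword n = X.n_rows, m = subsets.n_cols, k = subsets.n_rows;
  const uword n_edges = (type == 0) ? k * k : k * (k - 1) / 2;

  Rcpp::NumericVector conn(m, NA_REAL);
  Rcpp::IntegerVector fail(m, 0);
  mat edges_out;
  if (want_edges) edges_out.set_size(m, n_edges);
  if (want_edges) edges_out.fill(datum::nan);

  std::vector<uword> rows_i, rows_c;
  rows_i.reserve(n); rows_c.reserve(n);

  for (uword s = 0; s < m; ++s) {
    // rows where all k lagged predictors are observed, and the subset of
    // those where every outcome is also observed (common residual rows)
    rows_c.clear();
    std::vector<char> pred_ok(n, 0);
    for (uword r = 0; r < n; ++r) {
      bool okp = true;
      for (uword j = 0; j < k && okp; ++j)
        okp = std::isfinite(X(r, subsets(j, s) - 1));
      if (!okp) continue;
      pred_ok[r] = 1;
      bool okc = true;
      for (uword j = 0; j < k && okc; ++j)
        okc = std::isfinite(Y(r, subsets(j, s) - 1));
      if (okc) rows_c.push_back(r);
    }

    mat B(k, k);
    mat resid_c(rows_c.size(), k);
    bool bad = false;
    int code = 0;

    for (uword i = 0; i < k && !bad; ++i) {
      const uword ci = subsets(i, s) - 1;
      rows_i.clear();
      for (uword r = 0; r < n; ++r)
        if (pred_ok[r] && std::isfinite(Y(r, ci))) rows_i.push_back(r);
      if (rows_i.size() < k + 2) { bad = true; code = 1; break; }

      mat D(rows_i.size(), k + 1);
      vec y(rows_i.size());
      for (uword r = 0; r < rows_i.size(); ++r) {
        D(r, 0) = 1.0;
        for (uword j = 0; j < k; ++j)
          D(r, j + 1) = X(rows_i[r], subsets(j, s) - 1);
        y(r) = Y(rows_i[r], ci);
      }
      vec beta;
      if (!ols(D, y, beta)) { bad = true; code = 2; break; }
      B.row(i) = beta.subvec(1, k).t();

      if (type != 0) {
        for (uword r = 0; r < rows_c.size(); ++r) {
          const uword rr = rows_c[r];
          double fit = beta(0);
          for (uword j = 0; j < k; ++j)
            fit += beta(j + 1) * X(rr, subsets(j, s) - 1);
          resid_c(r, i) = Y(rr, ci) - fit;
        }
      }
    }

    if (!bad && type != 0 && rows_c.size() < k + 2) { bad = true; code = 1; }

    mat E; // final edge matrix
    if (!bad) {
      if (type == 0) {
        E = B;
      } else {
        mat S = cov(resid_c);
        if (type == 1) {
          mat P;
          if (!inv_sympd(P, S)) { bad = true; code = 2; }
          else {
            vec d = sqrt(P.diag());
            E = -P / (d * d.t());
          }
        } else {
          vec d = sqrt(S.diag());
          if (any(d == 0)) { bad = true; code = 2; }
          else E = S / (d * d.t());
        }
        if (!bad) { E.diag().zeros(); E = (E + E.t()) / 2; }
      }
    }

    if (bad) { fail[s] = code; continue; }

    if (type == 0) {
      conn[s] = accu(E);
    } else {
      double tot = 0;
      for (uword j = 1; j < k; ++j)
        for (uword i = 0; i < j; ++i) tot += E(i, j);
      conn[s] = tot;
    }
    if (want_edges) {
      if (type == 0) {
        edges_out.row(s) = vectorise(E).t();
      } else {
        uword pos = 0;
        for (uword j = 1; j < k; ++j)
          for (uword i = 0; i < j; ++i) edges_out(s, pos++) = E(i, j);
      }
    }
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("connectivity") = conn,
                                      Rcpp::Named("fail") = fail);
  if (want_edges) out["edges"] = Rcpp::wrap(edges_out);
  return out;
}
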