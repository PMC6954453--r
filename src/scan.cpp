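// Per-SNP generalized linear model scans.
//
// Each SNP gets its own fit: trait ~ intercept (+ covariates) + SNP for the
// marginal scan, or trait ~ intercept + E (+ covariates) + SNP + SNP*E for
// the interaction scan.  Only the coefficient of interest (the appended
// last column) and its standard error are returned.  Gaussian fits use the
// normal equations; binomial fits use IRLS (tolerance 1e-8, at most 50
// iterations).  Degenerate predictors, rank deficiency, non-convergence
// and numerical separation are flagged, never silently imputed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static bool fit_gaussian(const mat& X, const vec& y,
                         double& beta_out, double& se_out, double& df_out) {
  const uword n = X.n_rows, p = X.n_cols;
  if (n <= p) return false;
  mat XtX = X.t() * X;
  mat R;
  if (!chol(R, XtX)) return false;
  vec b = solve(trimatu(R), solve(trimatl(R.t()), X.t() * y));
  double rss = accu(square(y - X * b));
  double df = static_cast<double>(n - p);
  double sigma2 = rss / df;
  // last diagonal entry of (X'X)^{-1} = R^{-1} R^{-T}
  mat Rinv = inv(trimatu(R));
  double v = sigma2 * dot(Rinv.row(p - 1), Rinv.row(p - 1));
  if (!(v > 0) || !std::isfinite(v)) return false;
  beta_out = b(p - 1);
  se_out = std::sqrt(v);
  df_out = df;
  return true;
}

static bool fit_binomial(const mat& X, const vec& y,
                         double& beta_out, double& se_out) {
  const uword p = X.n_cols;
  vec beta(p, fill::zeros);
  // warm start: intercept (first column) at the observed log-odds
  double ybar = mean(y);
  if (ybar > 0 && ybar < 1) beta(0) = std::log(ybar / (1.0 - ybar));
  bool converged = false;
  mat XtWX;
  for (int it = 0; it < 50; ++it) {
    vec eta = clamp(X * beta, -30.0, 30.0);
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
    vec z = eta + (y - mu) / w;
    XtWX = X.t() * (X.each_col() % w);
    vec XtWz = X.t() * (w % z);
    vec bn;
    if (!solve(bn, XtWX, XtWz, solve_opts::no_approx)) return false;
    if (!bn.is_finite()) return false;
    double delta = abs(bn - beta).max();
    beta = bn;
    if (delta < 1e-8) { converged = true; break; }
  }
  if (!converged) return false;
  if (abs(beta).max() > 1e2) return false; // separation guard
  // information at the solution
  vec eta = clamp(X * beta, -30.0, 30.0);
  vec mu = 1.0 / (1.0 + exp(-eta));
  vec w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
  XtWX = X.t() * (X.each_col() % w);
  mat covb;
  if (!inv_sympd(covb, XtWX)) return false;
  double v = covb(p - 1, p - 1);
  if (!(v > 0) || !std::isfinite(v)) return false;
  beta_out = beta(p - 1);
  se_out = std::sqrt(v);
  return true;
}

// [[Rcpp::export]]
Rcpp::List glm_scan_cpp(const arma::vec& y, const arma::mat& xbase,
                        const arma::mat& g, const arma::vec& e,
                        const bool interaction, const bool binomial) {
  const uword n = y.n_elem, L = g.n_cols;
  vec beta(L, fill::value(datum::nan));
  vec se(L, fill::value(datum::nan));
  vec df(L, fill::value(datum::nan));
  Rcpp::LogicalVector conv(L, false);

  for (uword l = 0; l < L; ++l) {
    vec gl = g.col(l);
    uvec keep = find_finite(gl);
    bool subset = keep.n_elem < n;
    if (keep.n_elem < xbase.n_cols + 3) continue;

    vec yl = subset ? y.elem(keep) : y;
    mat Xb = subset ? xbase.rows(keep) : xbase;
    vec gv = subset ? gl.elem(keep) : gl;

    if (var(gv) < 1e-12) continue; // monomorphic in the analysis sample

    mat X;
    if (interaction) {
      vec ev = subset ? e.elem(keep) : e;
      vec ge = gv % ev;
      if (var(ge) < 1e-12) continue; // constant interaction column
      X = join_rows(Xb, gv, ge);
    } else {
      X = join_rows(Xb, gv);
    }

    double b = 0, s = 0, d = 0;
    bool ok = binomial ? fit_binomial(X, yl, b, s)
                       : fit_gaussian(X, yl, b, s, d);
    if (ok) {
      beta(l) = b;
      se(l) = s;
      df(l) = d;
      conv(l) = true;
    }
  }

  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("se") = se,
                            Rcpp::Named("df") = df,
                            Rcpp::Named("converged") = conv);
}
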