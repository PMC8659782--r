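// PLS1 (NIPALS) cross-validated RMSE kernels.
//
// RMSECV is the selection criterion of the IRIV / VISSA / stepwise feature
// selectors; those algorithms evaluate thousands of column-subset sub-models
// per iteration, so the inner fit lives here rather than in R.  The latent
// response is the grade code (1-4); predictors are autoscaled on the training
// fold only.  For each fold the NIPALS components are extracted once and
// held-out predictions accumulated for every component count 1..ncomp_max;
// the reported RMSECV is the minimum over component counts (component choice
// by cross-validation, capped).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Held-out squared-error totals per component count for one train/test split.
// sse: accumulator (ncomp_max), n_test added to counts implicitly by caller.
static void pls1_fold_sse(const mat& Xtr, const vec& ytr,
                          const mat& Xte, const vec& yte,
                          const unsigned int ncomp_max, vec& sse) {
  const uword n = Xtr.n_rows, p = Xtr.n_cols;
  rowvec mu = mean(Xtr, 0);
  rowvec sd = stddev(Xtr, 0, 0);
  sd.elem(find(sd < 1e-12)).fill(1.0);
  mat X = (Xtr.each_row() - mu).each_row() / sd;
  mat Xt = (Xte.each_row() - mu).each_row() / sd;
  double ybar = mean(ytr);
  vec y = ytr - ybar;

  uword A = std::min<uword>(ncomp_max, std::min<uword>(p, n - 1));
  vec pred = zeros<vec>(Xte.n_rows);
  vec prev_err;  // squared errors at the deepest component reached
  uword a = 0;
  for (; a < A; ++a) {
    vec w = X.t() * y;
    double nw = norm(w);
    if (nw < 1e-12) break;  // X deflated to noise: no further signal
    w /= nw;
    vec t = X * w;
    double tt = dot(t, t);
    if (tt < 1e-24) break;
    vec pl = X.t() * t / tt;
    double q = dot(y, t) / tt;
    X -= t * pl.t();
    y -= q * t;
    vec tte = Xt * w;
    Xt -= tte * pl.t();
    pred += q * tte;
    vec err = square(yte - (pred + ybar));
    sse(a) += accu(err);
    prev_err = err;
  }
  // components that could not be extracted inherit the deepest model's error
  // (or the intercept-only error when no component was extracted)
  if (a == 0) prev_err = square(yte - ybar);
  for (uword b = a; b < ncomp_max; ++b) sse(b) += accu(prev_err);
}

static double cv_rmse(const mat& X, const vec& y, const ivec& fold,
                      const unsigned int ncomp_max) {
  int k = fold.max();
  vec sse = zeros<vec>(ncomp_max);
  for (int f = 1; f <= k; ++f) {
    uvec te = find(fold == f);
    uvec tr = find(fold != f);
    pls1_fold_sse(X.rows(tr), y.elem(tr), X.rows(te), y.elem(te),
                  ncomp_max, sse);
  }
  return sqrt(sse.min() / static_cast<double>(X.n_rows));
}

// [[Rcpp::export]]
double cpp_pls_cv_rmse(const arma::mat& X, const arma::vec& y,
                       const arma::ivec& fold, int ncomp_max) {
  return cv_rmse(X, y, fold, static_cast<unsigned int>(ncomp_max));
}

// RMSECV for many column-subset sub-models sharing one fold assignment.
// incl: B x p 0/1 matrix, one row per sub-model.
// [[Rcpp::export]]
arma::vec cpp_pls_cv_rmse_many(const arma::mat& X, const arma::vec& y,
                               const arma::ivec& fold,
                               const arma::umat& incl, int ncomp_max) {
  const uword B = incl.n_rows;
  vec out(B);
  for (uword b = 0; b < B; ++b) {
    uvec cols = find(incl.row(b).t() == 1);
    if (cols.n_elem == 0) { out(b) = datum::nan; continue; }
    out(b) = cv_rmse(X.cols(cols), y, fold,
                     static_cast<unsigned int>(ncomp_max));
  }
  return out;
}
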