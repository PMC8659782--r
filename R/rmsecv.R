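# Cross-validated RMSE of the internal latent-variable regression.
#
# Grades are coded 1 (I) to 4 (IV) and regressed on the feature columns with
# the package's own PLS1 (NIPALS) fit, predictors autoscaled per training
# fold; the number of latent components is chosen by the cross-validation
# itself (minimum CV error over 1..ncomp_max components).  This score is what
# IRIV, VISSA and the stepwise selector compare sub-models by.

make_folds <- function(n, k, seed) {
  if (k < 2L) abort("`k` must be >= 2")
  if (n < k) abort("fewer rows than folds")
  withr::with_seed(as.integer(seed),
                   sample(rep(seq_len(k), length.out = n)))
}

# Coerce (x, y) inputs: x a feature table (possibly with grade column) or a
# numeric matrix; y grade labels or numeric codes.
as_xy <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    if (is.null(y) && "grade" %in% names(x)) y <- x$grade
    x <- as.matrix(x[, feature_columns(x), drop = FALSE])
  }
  if (is.null(y)) abort("no response: supply `y` or a `grade` column")
  storage.mode(x) <- "double"
  list(x = x, y = grade_code(y))
}

#' Cross-validated RMSE of grade codes regressed on features
#'
#' `RMSECV = sqrt(sum((Y - Y_v)^2) / n)` where `Y` are the grade codes 1-4
#' and `Y_v` the held-out predictions of the internal PLS1 regression over
#' `k` folds.
#'
#' @param x A feature table (its `grade` column supplies `y`) or numeric
#'   matrix of predictors.
#' @param y Grade labels or numeric codes; taken from `x` when omitted.
#' @param k Number of folds (>= 2).
#' @param ncomp_max Maximum number of PLS components considered (default 10).
#' @param seed Seed for the fold assignment.
#' @return A single non-negative score.
#' @export
#' @examples
#' tab <- generate_feature_table(planted_table_spec(n_samples = 60, seed = 3))
#' rmsecv(tab)
rmsecv <- function(x, y = NULL, k = 5L, ncomp_max = 10L, seed = 1L) {
  xy <- as_xy(x, y)
  folds <- make_folds(nrow(xy$x), k, seed)
  cpp_pls_cv_rmse(xy$x, xy$y, folds,
                  as.integer(min(ncomp_max, ncol(xy$x))))
}

# RMSECV for many column subsets of one matrix, sharing one fold assignment.
rmsecv_many <- function(x, y, incl, folds, ncomp_max = 10L) {
  cpp_pls_cv_rmse_many(x, y, folds, incl, as.integer(ncomp_max))
}

# Intercept-only cross-validated RMSE: the no-signal baseline a selected
# subset must beat to count as informative.
baseline_rmse <- function(y, folds) {
  pred <- numeric(length(y))
  for (f in unique(folds)) pred[folds == f] <- mean(y[folds != f])
  root_mean_square(y - pred)
}
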