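# Feature selection: IRIV, VISSA and stepwise regression, all scored by the
# cross-validated RMSE of grade codes (rmsecv).

new_selection_result <- function(method, selected, trace, seed,
                                 classification = NULL, weights = NULL,
                                 config = list()) {
  structure(
    list(method = method, selected = selected, trace = trace,
         classification = classification, weights = weights,
         seed = seed, config = config),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: %s>\n", x$method))
  cat(sprintf("  selected %d feature(s): %s\n", length(x$selected),
              paste(x$selected, collapse = ", ")))
  if (nrow(x$trace) > 0)
    cat(sprintf("  final RMSECV: %.4f\n", x$trace$rmsecv[nrow(x$trace)]))
  invisible(x)
}

#' Tidiers and plots for selection results
#'
#' `tidy()` returns the RMSECV trace (one row per step), `glance()` a one-row
#' summary, and `autoplot()` the trace colored by phase.
#'
#' @param x,object A `selection_result`.
#' @param ... Unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @export
tidy.selection_result <- function(x, ...) x$trace

#' @rdname tidy.selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_selected = length(x$selected),
    final_rmsecv = if (nrow(x$trace)) x$trace$rmsecv[nrow(x$trace)] else NA_real_,
    seed = x$seed
  )
}

#' @rdname tidy.selection_result
#' @export
autoplot.selection_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$step, y = .data$rmsecv,
                               colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "step", y = "RMSECV",
                  title = sprintf("%s selection trace", object$method)) +
    ggplot2::theme_minimal()
}

# Random inclusion matrix with no empty rows.
sample_inclusion <- function(n_sub, prob) {
  p <- length(prob)
  m <- matrix(rbinom(n_sub * p, 1L, rep(prob, each = n_sub)), n_sub, p)
  empty <- rowSums(m) == 0L
  if (any(empty)) {
    live <- which(prob > 0)
    if (length(live) == 0L) live <- seq_len(p)
    m[cbind(which(empty),
            live[sample.int(length(live), sum(empty), replace = TRUE)])] <- 1L
  }
  m
}

# Backward elimination: greedily drop the variable whose removal gives the
# lowest RMSECV, as long as that score does not exceed the current one.
# One fold assignment is used for the whole phase, so successive scores are
# comparable and the recorded trace is monotone non-increasing.
backward_eliminate <- function(x, y, vars, k, seed, ncomp_max, trace,
                               step0) {
  folds <- make_folds(nrow(x), k, derive_seed(seed, "elimination"))
  current <- rmsecv_many(x[, vars, drop = FALSE], y,
                         matrix(1L, 1, length(vars)), folds, ncomp_max)
  step <- step0
  trace <- dplyr::bind_rows(trace, tibble::tibble(
    step = step, phase = "elimination", rmsecv = current,
    n_features = length(vars)))
  while (length(vars) > 1L) {
    incl <- 1L - diag(length(vars))
    scores <- rmsecv_many(x[, vars, drop = FALSE], y, incl, folds, ncomp_max)
    best <- which.min(scores)
    if (scores[best] > current) break
    current <- scores[best]
    vars <- vars[-best]
    step <- step + 1L
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step, phase = "elimination", rmsecv = current,
      n_features = length(vars)))
  }
  list(vars = vars, trace = trace)
}

#' IRIV feature selection
#'
#' Iteratively retains informative variables.  Each round draws `n_sub`
#' random binary sub-models over the retained variables and, for every
#' variable, compares the paired RMSECV distributions of sub-models with the
#' variable included versus excluded (each sampled sub-model is re-evaluated
#' with that one variable flipped).  Variables are classified by the sign of
#' the mean paired difference (excluded minus included) and the significance
#' of a paired Wilcoxon test: strongly informative (positive, significant),
#' weakly informative (positive, not significant), uninformative (negative,
#' not significant) or interfering (negative, significant).  Uninformative
#' and interfering variables are dropped and the process repeats until none
#' remain (or `max_iter` rounds), after which backward elimination removes
#' variables one at a time while the RMSECV does not increase.
#'
#' @param table A feature table with a `grade` column.
#' @param k Folds for RMSECV.
#' @param ncomp_max Maximum PLS components.
#' @param n_sub Number of sampled sub-models per round.
#' @param alpha Significance level of the paired test.
#' @param max_iter Maximum classification rounds.
#' @param seed Integer seed (folds and sampling).
#' @return A `selection_result` with the per-round variable classification
#'   history.
#' @export
iriv_select <- function(table, k = 5L, ncomp_max = 10L, n_sub = 500L,
                        alpha = 0.05, max_iter = 20L, seed = 1L) {
  xy <- as_xy(table)
  vars <- colnames(xy$x)
  if (length(vars) < 2L) abort("need at least 2 features")
  if (nrow(xy$x) < 20L) abort("need at least 20 samples")
  if (length(unique(xy$y)) < 2L) abort("degenerate label column")
  trace <- tibble::tibble(step = integer(), phase = character(),
                          rmsecv = double(), n_features = integer())
  history <- list()
  step <- 0L

  withr::with_seed(derive_seed(seed, "iriv"), {
    retained <- vars
    for (round in seq_len(max_iter)) {
      p <- length(retained)
      if (p < 2L) break
      # fresh fold assignment every round: a variable survives only if it
      # helps across independent splits, not on one lucky fold draw
      folds <- make_folds(nrow(xy$x), k,
                          derive_seed(seed, paste0("folds-", round)))
      xm <- xy$x[, retained, drop = FALSE]
      m <- sample_inclusion(n_sub, rep(0.5, p))
      rmse0 <- rmsecv_many(xm, xy$y, m, folds, ncomp_max)
      dmean <- pval <- numeric(p)
      for (i in seq_len(p)) {
        mi <- m
        mi[, i] <- 1L - mi[, i]
        rmse_i <- rmsecv_many(xm, xy$y, mi, folds, ncomp_max)
        incl <- ifelse(m[, i] == 1L, rmse0, rmse_i)
        excl <- ifelse(m[, i] == 1L, rmse_i, rmse0)
        ok <- is.finite(incl) & is.finite(excl)
        dmean[i] <- mean(excl[ok] - incl[ok])
        pval[i] <- tryCatch(
          suppressWarnings(wilcox.test(excl[ok], incl[ok],
                                       paired = TRUE)$p.value),
          error = function(e) 1)
      }
      category <- dplyr::case_when(
        dmean > 0 & pval < alpha ~ "strong",
        dmean > 0 ~ "weak",
        pval < alpha ~ "interfering",
        TRUE ~ "uninformative"
      )
      history[[round]] <- tibble::tibble(
        round = round, variable = retained,
        dmean = dmean, p_value = pval, category = category)
      step <- step + 1L
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        step = step, phase = "classification",
        rmsecv = stats::median(rmse0[is.finite(rmse0)]),
        n_features = p))
      keep <- category %in% c("strong", "weak")
      if (!any(keep)) {
        retained <- retained[which.max(dmean)]
        break
      }
      if (all(keep)) { retained <- retained[keep]; break }
      retained <- retained[keep]
    }
    be <- backward_eliminate(xy$x[, retained, drop = FALSE], xy$y, retained,
                             k, seed, ncomp_max, trace, step + 1L)
    base <- baseline_rmse(xy$y, make_folds(nrow(xy$x), k,
                                           derive_seed(seed, "elimination")))
    if (be$trace$rmsecv[nrow(be$trace)] > 0.95 * base) {
      warn("all-noise table: no subset beats the intercept-only baseline")
      be$vars <- character()
    }
    new_selection_result(
      "IRIV", be$vars, be$trace, seed,
      classification = dplyr::bind_rows(history),
      config = list(k = k, ncomp_max = ncomp_max, n_sub = n_sub,
                    alpha = alpha, max_iter = max_iter))
  })
}

#' VISSA feature selection
#'
#' Variable iterative space shrinkage approach.  Each iteration draws
#' `n_sub` sub-models by weighted binary sampling (initial inclusion weight
#' 0.5 per variable), keeps the best `elite_frac` fraction by RMSECV, and
#' updates every variable's weight to its frequency among the kept models.
#' Iteration stops when the weights have all shrunk to 0 or 1 or the best
#' RMSECV has stopped improving; the variables with final weight 1 are
#' selected.
#'
#' @inheritParams iriv_select
#' @param elite_frac Fraction of sub-models kept per iteration.
#' @param max_iter Maximum iterations.
#' @param patience Iterations without improvement tolerated before stopping.
#' @return A `selection_result` with the per-iteration weight trace.
#' @export
vissa_select <- function(table, k = 5L, ncomp_max = 10L, n_sub = 500L,
                         elite_frac = 0.05, max_iter = 50L, patience = 3L,
                         seed = 1L) {
  xy <- as_xy(table)
  vars <- colnames(xy$x)
  if (length(vars) < 2L) abort("need at least 2 features")
  if (nrow(xy$x) < 20L) abort("need at least 20 samples")
  if (length(unique(xy$y)) < 2L) abort("degenerate label column")
  p <- length(vars)
  n_elite <- max(1L, ceiling(elite_frac * n_sub))

  eval_folds <- make_folds(nrow(xy$x), k, derive_seed(seed, "vissa-eval"))
  withr::with_seed(derive_seed(seed, "vissa"), {
    w <- rep(0.5, p)
    trace <- tibble::tibble(step = integer(), phase = character(),
                            rmsecv = double(), n_features = integer())
    wtrace <- list()
    best_set <- character()
    best_score <- Inf
    stall <- 0L
    for (it in seq_len(max_iter)) {
      m <- sample_inclusion(n_sub, w)
      # weight-1 variables are always in, weight-0 always out; folds are
      # redrawn per iteration so weights track split-independent merit
      folds <- make_folds(nrow(xy$x), k,
                          derive_seed(seed, paste0("folds-", it)))
      rmse <- rmsecv_many(xy$x, xy$y, m, folds, ncomp_max)
      elite <- order(rmse)[seq_len(n_elite)]
      w <- colMeans(m[elite, , drop = FALSE])
      wtrace[[it]] <- tibble::tibble(iteration = it, variable = vars,
                                     weight = w)
      # the monitored RMSECV is that of the current weight-1 set, always on
      # one fixed evaluation fold assignment so scores are comparable across
      # iterations: iteration stops once this score stops improving, and the
      # best-scoring set is what the shrinkage returns
      fixed <- which(w == 1)
      score <- if (length(fixed) > 0L)
        rmsecv_many(xy$x[, fixed, drop = FALSE], xy$y,
                    matrix(1L, 1, length(fixed)), eval_folds, ncomp_max)
      else min(rmse, na.rm = TRUE)
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        step = it, phase = "shrinkage", rmsecv = score,
        n_features = sum(w > 0)))
      if (length(fixed) > 0L && score < best_score - 1e-12) {
        best_score <- score
        best_set <- vars[fixed]
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (all(w %in% c(0, 1)) || stall >= patience) break
    }
    # final subset choice: rank variables by their mean sampling weight over
    # the iterations (consistently useful variables absorb at weight 1 early
    # and rank top) and evaluate the RMSECV of every top-k set on the fixed
    # evaluation folds; the selected set is the best-scoring one.  The
    # resulting RMSECV-versus-k curve falls to a minimum and rises again as
    # chance-correlated noise variables enter.
    wt <- dplyr::bind_rows(wtrace)
    mean_w <- tapply(wt$weight, wt$variable, mean)[vars]
    ranked <- vars[order(-w, -mean_w)]
    k_max <- max(1L, sum(w > 0))
    incl <- matrix(0L, k_max, p, dimnames = list(NULL, vars))
    for (kk in seq_len(k_max)) incl[kk, ranked[seq_len(kk)]] <- 1L
    k_scores <- rmsecv_many(xy$x, xy$y, incl, eval_folds, ncomp_max)
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = max(trace$step) + seq_len(k_max), phase = "ranking",
      rmsecv = k_scores, n_features = seq_len(k_max)))
    selected <- ranked[seq_len(which.min(k_scores))]
    if (min(k_scores) > 0.95 * baseline_rmse(xy$y, eval_folds)) {
      warn("all-noise table: no subset beats the intercept-only baseline")
      selected <- character()
    }
    new_selection_result(
      "VISSA", selected, trace, seed,
      weights = dplyr::bind_rows(wtrace),
      config = list(k = k, ncomp_max = ncomp_max, n_sub = n_sub,
                    elite_frac = elite_frac, max_iter = max_iter))
  })
}

#' Stepwise regression feature selection
#'
#' Classical forward/backward stepwise regression of the grade codes on the
#' features: the variable with the most significant partial F statistic is
#' entered while its p-value is below `p_enter`, then any entered variable
#' whose partial F p-value exceeds `p_remove` is removed, until no change.
#' Deterministic; zero-variance and collinear-duplicate columns are never
#' entered (their partial F is undefined or nil).
#'
#' @inheritParams iriv_select
#' @param p_enter Entry significance threshold.
#' @param p_remove Removal significance threshold (> `p_enter`).
#' @param seed Seed used only for the reported RMSECV trace folds.
#' @return A `selection_result`.
#' @export
sra_select <- function(table, p_enter = 0.05, p_remove = 0.10, k = 5L,
                       seed = 1L) {
  xy <- as_xy(table)
  vars <- colnames(xy$x)
  df <- as.data.frame(xy$x)
  df$.y <- xy$y
  current <- character()
  folds <- make_folds(nrow(df), k, derive_seed(seed, "folds"))
  fit_for <- function(sel) {
    fml <- if (length(sel) == 0L) .y ~ 1 else
      stats::reformulate(sprintf("`%s`", sel), response = ".y")
    lm(fml, data = df)
  }
  score_of <- function(sel) {
    if (length(sel) == 0L) return(NA_real_)
    rmsecv_many(xy$x[, sel, drop = FALSE], df$.y,
                matrix(1L, 1, length(sel)), folds, 10L)
  }
  trace <- tibble::tibble(step = integer(), phase = character(),
                          rmsecv = double(), n_features = integer())
  step <- 0L
  repeat {
    changed <- FALSE
    cands <- setdiff(vars, current)
    cands <- cands[vapply(cands, function(v) sd(df[[v]]) > 0, TRUE)]
    if (length(cands) > 0L) {
      fit <- fit_for(current)
      scope <- stats::reformulate(sprintf("`%s`", c(current, cands)))
      tab <- suppressWarnings(add1(fit, scope = scope, test = "F"))
      rn <- gsub("`", "", rownames(tab))
      pv <- tab[["Pr(>F)"]][match(cands, rn)]
      pv[is.na(pv)] <- 1
      if (min(pv) < p_enter) {
        current <- c(current, cands[which.min(pv)])
        changed <- TRUE
        step <- step + 1L
        trace <- dplyr::bind_rows(trace, tibble::tibble(
          step = step, phase = "forward", rmsecv = score_of(current),
          n_features = length(current)))
      }
    }
    while (length(current) > 0L) {
      fit <- fit_for(current)
      tab <- suppressWarnings(drop1(fit, test = "F"))
      rn <- gsub("`", "", rownames(tab))
      pv <- tab[["Pr(>F)"]][match(current, rn)]
      pv[is.na(pv)] <- 1
      if (max(pv) <= p_remove) break
      current <- current[-which.max(pv)]
      changed <- TRUE
      step <- step + 1L
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        step = step, phase = "backward", rmsecv = score_of(current),
        n_features = length(current)))
    }
    if (!changed) break
  }
  if (length(current) == 0L)
    warn("stepwise regression entered no variable: all-noise table?")
  new_selection_result(
    "SRA", current, trace, seed,
    config = list(p_enter = p_enter, p_remove = p_remove, k = k))
}
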