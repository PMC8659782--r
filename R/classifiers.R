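# Grade classifiers: RBF-SVM (via libsvm's one-vs-one), a single-hidden-layer
# extreme learning machine and a backpropagation network, all on features
# z-scored with training-set statistics.

#' Stratified train/test split of a feature table
#'
#' Splits each grade class at `train_fraction` (rounded per class), so class
#' balance is preserved on both sides; e.g. 1800 balanced records at 0.7
#' yield 1260 training and 540 test rows, 315/135 per class.
#'
#' @param table A feature table with a `grade` column.
#' @param train_fraction Fraction in (0, 1) per class.
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
stratified_split <- function(table, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    abort("`train_fraction` must be in (0, 1)")
  g <- grade_factor(table$grade)
  if (any(table(g[!is.na(g)]) < 2L & table(g[!is.na(g)]) > 0L))
    abort("every class needs at least 2 samples")
  idx_train <- withr::with_seed(as.integer(seed), {
    unlist(lapply(levels(g), function(lv) {
      rows <- which(g == lv)
      if (length(rows) == 0L) return(integer())
      n_tr <- round(train_fraction * length(rows))
      sample(rows, n_tr)
    }))
  })
  list(train = table[sort(idx_train), , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), idx_train), , drop = FALSE])
}

scaler_fit <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s < 1e-12] <- 1
  list(center = mu, scale = s)
}

scaler_apply <- function(x, sc) {
  scale(x, center = sc$center, scale = sc$scale)[, , drop = FALSE]
}

new_root_model <- function(family, fit, scaler, levels, extra = list()) {
  structure(c(list(family = family, fit = fit, scaler = scaler,
                   levels = levels), extra),
            class = "root_model")
}

#' @export
print.root_model <- function(x, ...) {
  cat(sprintf("<root_model: %s, %d features, classes %s>\n", x$family,
              length(x$scaler$center), paste(x$levels, collapse = "/")))
  invisible(x)
}

#' Train an RBF support vector machine grade classifier
#'
#' One-vs-one multiclass soft-margin SVM with kernel
#' `exp(-g * ||u - v||^2)`, fitted on features z-scored with training-set
#' statistics.
#'
#' @param x Feature table (its `grade` column supplies `y`) or numeric
#'   matrix.
#' @param y Grade labels; taken from `x` when omitted.
#' @param cost Penalty parameter c (> 0).
#' @param gamma Kernel width g (> 0); defaults to 1 / n_features.
#' @return A `root_model`.
#' @export
train_svm <- function(x, y = NULL, cost = 1, gamma = NULL) {
  xy <- as_xy_class(x, y)
  if (cost <= 0) abort("`cost` must be > 0")
  if (is.null(gamma)) gamma <- 1 / ncol(xy$x)
  if (gamma <= 0) abort("`gamma` must be > 0")
  if (nlevels(droplevels(xy$y)) < 2L) abort("need at least 2 classes")
  sc <- scaler_fit(xy$x)
  xs <- scaler_apply(xy$x, sc)
  fit <- e1071::svm(xs, droplevels(xy$y), type = "C-classification",
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  new_root_model("svm", fit, sc, levels(droplevels(xy$y)),
                 list(cost = cost, gamma = gamma))
}

#' Train an extreme learning machine grade classifier
#'
#' Single hidden layer with seeded random input weights and biases, sigmoid
#' activation, and ridge-regularized least-squares output weights on one-hot
#' targets; prediction is by argmax.
#'
#' @inheritParams train_svm
#' @param n_hidden Hidden-unit count (>= 1).
#' @param ridge Ridge penalty for the output solve.
#' @param seed Integer seed for the random hidden layer.
#' @return A `root_model`.
#' @export
train_elm <- function(x, y = NULL, n_hidden = 100L, ridge = 1e-6,
                      seed = 1L) {
  xy <- as_xy_class(x, y)
  if (n_hidden < 1L) abort("`n_hidden` must be >= 1")
  sc <- scaler_fit(xy$x)
  xs <- scaler_apply(xy$x, sc)
  p <- ncol(xs)
  lv <- levels(droplevels(xy$y))
  withr::with_seed(as.integer(seed), {
    w_in <- matrix(runif(n_hidden * p, -1, 1), p, n_hidden)
    b_in <- runif(n_hidden, -1, 1)
  })
  h <- 1 / (1 + exp(-(xs %*% w_in + rep(b_in, each = nrow(xs)))))
  t_hot <- 1 * outer(as.character(xy$y), lv, "==")
  beta <- solve(crossprod(h) + ridge * diag(n_hidden), crossprod(h, t_hot))
  new_root_model("elm", list(w_in = w_in, b_in = b_in, beta = beta), sc, lv,
                 list(n_hidden = n_hidden, seed = seed))
}

#' Train a backpropagation network grade classifier
#'
#' One hidden sigmoid layer trained by full-batch gradient descent on the
#' softmax cross-entropy, with seeded initialization.
#'
#' @inheritParams train_svm
#' @param n_hidden Hidden-layer size.
#' @param learning_rate Gradient-descent step size.
#' @param epochs Number of full-batch epochs (0 leaves the random
#'   initialization untouched).
#' @param seed Integer seed.
#' @return A `root_model`.
#' @export
train_bp <- function(x, y = NULL, n_hidden = 20L, learning_rate = 0.01,
                     epochs = 1000L, seed = 1L) {
  xy <- as_xy_class(x, y)
  sc <- scaler_fit(xy$x)
  xs <- scaler_apply(xy$x, sc)
  n <- nrow(xs); p <- ncol(xs)
  lv <- levels(droplevels(xy$y))
  nc <- length(lv)
  t_hot <- 1 * outer(as.character(xy$y), lv, "==")
  withr::with_seed(as.integer(seed), {
    w1 <- matrix(rnorm(p * n_hidden, 0, 0.1), p, n_hidden)
    b1 <- rep(0, n_hidden)
    w2 <- matrix(rnorm(n_hidden * nc, 0, 0.1), n_hidden, nc)
    b2 <- rep(0, nc)
  })
  for (ep in seq_len(epochs)) {
    h <- 1 / (1 + exp(-(xs %*% w1 + rep(b1, each = n))))
    z <- h %*% w2 + rep(b2, each = n)
    z <- z - apply(z, 1, max)
    prob <- exp(z) / rowSums(exp(z))
    loss <- -mean(log(rowSums(prob * t_hot) + 1e-300))
    if (!is.finite(loss) || max(abs(w1)) > 1e6 || max(abs(w2)) > 1e6)
      abort("training diverged; lower `learning_rate`")
    dz <- (prob - t_hot) / n
    dw2 <- crossprod(h, dz)
    db2 <- colSums(dz)
    dh <- dz %*% t(w2) * h * (1 - h)
    dw1 <- crossprod(xs, dh)
    db1 <- colSums(dh)
    w2 <- w2 - learning_rate * dw2; b2 <- b2 - learning_rate * db2
    w1 <- w1 - learning_rate * dw1; b1 <- b1 - learning_rate * db1
  }
  new_root_model("bp", list(w1 = w1, b1 = b1, w2 = w2, b2 = b2), sc, lv,
                 list(n_hidden = n_hidden, learning_rate = learning_rate,
                      epochs = epochs, seed = seed))
}

# (x, y) coercion for classifiers: y stays a factor.
as_xy_class <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    if (is.null(y) && "grade" %in% names(x)) y <- x$grade
    x <- as.matrix(x[, feature_columns(x), drop = FALSE])
  }
  if (is.null(y)) abort("no labels: supply `y` or a `grade` column")
  storage.mode(x) <- "double"
  list(x = x, y = grade_factor(y))
}

#' Predict grades with a trained model
#'
#' @param object A `root_model`.
#' @param newdata Feature table or numeric matrix with the training columns.
#' @param ... Unused.
#' @return Factor of predicted grades.
#' @export
predict.root_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata))
    newdata <- as.matrix(newdata[, feature_columns(newdata), drop = FALSE])
  storage.mode(newdata) <- "double"
  xs <- scaler_apply(newdata, object$scaler)
  pred <- switch(
    object$family,
    svm = as.character(predict(object$fit, xs)),
    elm = {
      h <- 1 / (1 + exp(-(xs %*% object$fit$w_in +
                            rep(object$fit$b_in, each = nrow(xs)))))
      object$levels[max.col(h %*% object$fit$beta, ties.method = "first")]
    },
    bp = {
      h <- 1 / (1 + exp(-(xs %*% object$fit$w1 +
                            rep(object$fit$b1, each = nrow(xs)))))
      z <- h %*% object$fit$w2 + rep(object$fit$b2, each = nrow(xs))
      object$levels[max.col(z, ties.method = "first")]
    },
    abort("unknown model family")
  )
  grade_factor(pred)
}

#' Evaluate a grade classifier
#'
#' Computes overall accuracy (percent), per-class accuracy, the macro
#' average of the per-class accuracies, and the confusion matrix (true
#' grades in rows, predictions in columns).
#'
#' @param model A `root_model`.
#' @param x Feature table or matrix to evaluate on.
#' @param y True grades; taken from `x` when omitted.
#' @return An `eval_report` object.
#' @export
evaluate <- function(model, x, y = NULL) {
  xy <- as_xy_class(x, y)
  if (!all(as.character(unique(xy$y)) %in% model$levels))
    abort("labels outside the training label set")
  pred <- predict(model, xy$x)
  lv <- model$levels
  conf <- table(true = factor(xy$y, levels = lv),
                predicted = factor(pred, levels = lv))
  acc <- 100 * sum(diag(conf)) / sum(conf)
  per_class <- 100 * diag(conf) / pmax(rowSums(conf), 1L)
  structure(
    list(accuracy = acc, per_class = per_class,
         macro_accuracy = mean(per_class[rowSums(conf) > 0]),
         confusion = unclass(conf), n = sum(conf)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: accuracy %.3f%% on %d samples>\n",
              x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' Tidiers and plots for evaluation reports
#'
#' `tidy()` returns the confusion matrix in long form, `glance()` a one-row
#' accuracy summary, and `autoplot()` a confusion-matrix heat map.
#'
#' @param x,object An `eval_report`.
#' @param ... Unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::as_tibble(as.data.frame(as.table(x$confusion),
                                  stringsAsFactors = FALSE)) |>
    stats::setNames(c("true", "predicted", "count"))
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_accuracy = x$macro_accuracy,
                 n = x$n)
}

#' @rdname tidy.eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidy.eval_report(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("Confusion matrix (accuracy %.2f%%)",
                                  object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Stratified k-fold cross-validated SVM accuracy
#'
#' Mean held-out accuracy (percent) of [train_svm()] over `k` stratified
#' folds; deterministic given the seed.  This is the fitness function of the
#' metaheuristic tuners.
#'
#' @param x Feature table or matrix.
#' @param y Grade labels; taken from `x` when omitted.
#' @param cost,gamma SVM parameters.
#' @param k Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @return Accuracy in percent.
#' @export
cv_accuracy <- function(x, y = NULL, cost = 1, gamma = NULL, k = 5L,
                        seed = 1L) {
  xy <- as_xy_class(x, y)
  g <- droplevels(xy$y)
  folds <- withr::with_seed(as.integer(seed), {
    f <- integer(length(g))
    for (lv in levels(g)) {
      rows <- which(g == lv)
      f[rows] <- sample(rep(seq_len(k), length.out = length(rows)))
    }
    f
  })
  correct <- 0L
  for (fold in seq_len(k)) {
    if (!any(folds == fold)) next
    tr <- folds != fold
    model <- train_svm(xy$x[tr, , drop = FALSE], xy$y[tr],
                       cost = cost, gamma = gamma)
    pred <- predict(model, xy$x[!tr, , drop = FALSE])
    correct <- correct + sum(pred == xy$y[!tr])
  }
  100 * correct / length(g)
}
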