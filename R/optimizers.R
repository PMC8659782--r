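# Metaheuristic tuning of the SVM's penalty c and kernel width g, with
# 5-fold cross-validated accuracy as the (maximized) fitness.

#' Rectangular search space
#'
#' @param lower,upper Named or unnamed numeric vectors of per-dimension
#'   bounds; all positive, with `lower < upper` elementwise.
#' @return An object of class `search_space`.
#' @export
search_space <- function(lower = c(c = 0.01, g = 0.01),
                         upper = c(c = 100, g = 100)) {
  if (length(lower) != length(upper) || any(lower >= upper))
    abort("`lower` must be < `upper` elementwise")
  if (any(lower <= 0)) abort("bounds must be positive")
  structure(list(lower = unname(lower), upper = unname(upper),
                 names = names(lower) %||% paste0("x", seq_along(lower))),
            class = "search_space")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_opt_result <- function(algorithm, best, best_fitness, trace,
                           best_iteration, seed) {
  structure(list(algorithm = algorithm, best = best,
                 best_fitness = best_fitness, trace = trace,
                 best_iteration = best_iteration, seed = seed),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("<opt_result: %s>\n  best (%s) = (%s), fitness %.4f (iteration %d)\n",
              x$algorithm, paste(names(x$best), collapse = ", "),
              paste(signif(x$best, 5), collapse = ", "),
              x$best_fitness, x$best_iteration))
  invisible(x)
}

#' Tidiers and plots for optimizer results
#'
#' `tidy()` returns the best-so-far fitness trace, `glance()` a one-row
#' summary, and `autoplot()` the convergence curve.
#'
#' @param x,object An `opt_result`.
#' @param ... Unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @export
tidy.opt_result <- function(x, ...) x$trace

#' @rdname tidy.opt_result
#' @export
glance.opt_result <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm,
                 !!!stats::setNames(as.list(x$best), names(x$best)),
                 best_fitness = x$best_fitness,
                 best_iteration = x$best_iteration, seed = x$seed)
}

#' @rdname tidy.opt_result
#' @export
autoplot.opt_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best fitness",
                  title = sprintf("%s convergence", object$algorithm)) +
    ggplot2::theme_minimal()
}

clip_to <- function(x, space) pmin(pmax(x, space$lower), space$upper)

eval_fitness <- function(fitness, x) {
  v <- tryCatch(fitness(x), error = function(e) NaN)
  if (!is.finite(v)) {
    warn("non-finite fitness; candidate discarded")
    return(-Inf)
  }
  v
}

# Shared bookkeeping: positions (pop x d) -> fitness vector.
eval_population <- function(fitness, pos) {
  apply(pos, 1, function(r) eval_fitness(fitness, r))
}

finish_opt <- function(algorithm, space, best_x, trace_vals, seed) {
  trace <- tibble::tibble(iteration = seq_along(trace_vals) - 1L,
                          best_fitness = trace_vals)
  best_fit <- trace_vals[length(trace_vals)]
  new_opt_result(algorithm,
                 stats::setNames(best_x, space$names),
                 best_fit, trace,
                 best_iteration = which(trace_vals >= best_fit - 1e-12)[1] - 1L,
                 seed = seed)
}

#' Grey wolf optimizer
#'
#' Canonical GWO maximization: the three best wolves (alpha, beta, delta)
#' lead; every wolf moves to the mean of three leader-guided positions with
#' the exploration coefficient `a` decreasing linearly from 2 to 0 over the
#' iterations.  Candidates are clipped to the bounds; the best-so-far trace
#' is monotone non-decreasing (iteration 0 records the initial population's
#' best).
#'
#' @param fitness Function of a parameter vector returning a finite scalar to
#'   maximize (non-finite values discard the candidate with a warning).
#' @param space A [search_space()].
#' @param pop Population size (>= 3 for the three leaders).
#' @param iters Number of iterations (>= 1).
#' @param seed Integer seed.
#' @return An `opt_result`.
#' @export
gwo <- function(fitness, space, pop = 20L, iters = 100L, seed = 1L) {
  stopifnot(inherits(space, "search_space"), pop >= 3L, iters >= 1L)
  d <- length(space$lower)
  withr::with_seed(as.integer(seed), {
    pos <- sapply(seq_len(d), function(j)
      runif(pop, space$lower[j], space$upper[j]))
    pos <- matrix(pos, pop, d)
    fit <- eval_population(fitness, pos)
    best_i <- which.max(fit)
    best_x <- pos[best_i, ]
    best_f <- fit[best_i]
    trace <- best_f
    for (it in seq_len(iters)) {
      a <- 2 - 2 * it / iters
      ord <- order(fit, decreasing = TRUE)
      leaders <- pos[ord[1:3], , drop = FALSE]
      for (w in seq_len(pop)) {
        xnew <- numeric(d)
        for (j in seq_len(d)) {
          guided <- vapply(1:3, function(l) {
            r1 <- runif(1); r2 <- runif(1)
            aa <- 2 * a * r1 - a
            cc <- 2 * r2
            leaders[l, j] - aa * abs(cc * leaders[l, j] - pos[w, j])
          }, 1)
          xnew[j] <- mean(guided)
        }
        pos[w, ] <- clip_to(xnew, space)
      }
      fit <- eval_population(fitness, pos)
      if (max(fit) > best_f) {
        best_f <- max(fit)
        best_x <- pos[which.max(fit), ]
      }
      trace <- c(trace, best_f)
    }
    finish_opt("GWO", space, best_x, trace, seed)
  })
}

#' Real-coded genetic algorithm
#'
#' Tournament selection (size 2), arithmetic crossover with probability
#' `p_cross`, per-gene Gaussian mutation with probability `p_mut`
#' (sd = 10% of the dimension range) and elitism of one; candidates are
#' clipped to the bounds.
#'
#' @inheritParams gwo
#' @param pop Even population size (>= 4).
#' @param p_cross,p_mut Crossover and mutation probabilities.
#' @return An `opt_result`.
#' @export
ga <- function(fitness, space, pop = 20L, iters = 100L, p_cross = 0.6,
               p_mut = 0.03, seed = 1L) {
  stopifnot(inherits(space, "search_space"), pop >= 4L, pop %% 2L == 0L,
            iters >= 1L, p_cross >= 0, p_cross <= 1, p_mut >= 0, p_mut <= 1)
  d <- length(space$lower)
  rng <- space$upper - space$lower
  withr::with_seed(as.integer(seed), {
    pos <- matrix(sapply(seq_len(d), function(j)
      runif(pop, space$lower[j], space$upper[j])), pop, d)
    fit <- eval_population(fitness, pos)
    best_i <- which.max(fit)
    best_x <- pos[best_i, ]
    best_f <- fit[best_i]
    trace <- best_f
    for (it in seq_len(iters)) {
      tournament <- function() {
        cand <- sample.int(pop, 2L)
        cand[which.max(fit[cand])]
      }
      children <- matrix(0, pop, d)
      for (m in seq_len(pop / 2L)) {
        p1 <- pos[tournament(), ]
        p2 <- pos[tournament(), ]
        if (runif(1) < p_cross) {
          al <- runif(1)
          c1 <- al * p1 + (1 - al) * p2
          c2 <- al * p2 + (1 - al) * p1
        } else {
          c1 <- p1; c2 <- p2
        }
        children[2 * m - 1L, ] <- c1
        children[2 * m, ] <- c2
      }
      mut <- matrix(runif(pop * d) < p_mut, pop, d)
      children[mut] <- children[mut] +
        rnorm(sum(mut), 0, 0.1 * rep(rng, each = pop)[mut])
      children <- t(apply(children, 1, clip_to, space = space))
      children[1L, ] <- best_x  # elitism
      pos <- children
      fit <- eval_population(fitness, pos)
      if (max(fit) > best_f) {
        best_f <- max(fit)
        best_x <- pos[which.max(fit), ]
      }
      trace <- c(trace, best_f)
    }
    finish_opt("GA", space, best_x, trace, seed)
  })
}

#' Particle swarm optimization
#'
#' Canonical constriction-style PSO: inertia-weighted velocity (0.729) with
#' cognitive and social pulls (1.494 each) toward the personal and global
#' bests; velocities are clamped to 20% of each dimension's range and
#' positions clipped to the bounds.
#'
#' @inheritParams gwo
#' @param pop Swarm size (>= 2).
#' @param inertia,c1,c2 PSO coefficients.
#' @return An `opt_result`.
#' @export
pso <- function(fitness, space, pop = 20L, iters = 100L, inertia = 0.729,
                c1 = 1.494, c2 = 1.494, seed = 1L) {
  stopifnot(inherits(space, "search_space"), pop >= 2L, iters >= 1L)
  d <- length(space$lower)
  rng <- space$upper - space$lower
  vmax <- 0.2 * rng
  withr::with_seed(as.integer(seed), {
    pos <- matrix(sapply(seq_len(d), function(j)
      runif(pop, space$lower[j], space$upper[j])), pop, d)
    vel <- matrix(sapply(seq_len(d), function(j)
      runif(pop, -vmax[j], vmax[j])), pop, d)
    fit <- eval_population(fitness, pos)
    pbest <- pos
    pbest_f <- fit
    gi <- which.max(fit)
    best_x <- pos[gi, ]
    best_f <- fit[gi]
    trace <- best_f
    for (it in seq_len(iters)) {
      r1 <- matrix(runif(pop * d), pop, d)
      r2 <- matrix(runif(pop * d), pop, d)
      vel <- inertia * vel + c1 * r1 * (pbest - pos) +
        c2 * r2 * (matrix(best_x, pop, d, byrow = TRUE) - pos)
      vel <- pmin(pmax(vel, rep(-vmax, each = pop)), rep(vmax, each = pop))
      pos <- t(apply(pos + vel, 1, clip_to, space = space))
      fit <- eval_population(fitness, pos)
      better <- fit > pbest_f
      pbest[better, ] <- pos[better, , drop = FALSE]
      pbest_f[better] <- fit[better]
      if (max(fit) > best_f) {
        best_f <- max(fit)
        best_x <- pos[which.max(fit), ]
      }
      trace <- c(trace, best_f)
    }
    finish_opt("PSO", space, best_x, trace, seed)
  })
}

# Default (c, g) search ranges per algorithm: GWO searches both on
# [0.01, 100]; GA up to g = 1000 and PSO c in [0.1, 100], g in [0.01, 1000].
default_space <- function(algorithm) {
  switch(algorithm,
         gwo = search_space(c(c = 0.01, g = 0.01), c(c = 100, g = 100)),
         ga  = search_space(c(c = 0.01, g = 0.01), c(c = 100, g = 1000)),
         pso = search_space(c(c = 0.1, g = 0.01), c(c = 100, g = 1000)))
}

#' Tune SVM hyperparameters with a metaheuristic
#'
#' Maximizes the stratified 5-fold cross-validated accuracy of the RBF-SVM
#' over (c, g) with the grey wolf optimizer, genetic algorithm or particle
#' swarm optimization.  Fitness values are cached on (c, g) rounded to six
#' significant digits, so revisited candidates cost nothing.
#'
#' @param table A feature table with a `grade` column.
#' @param algorithm `"gwo"`, `"ga"` or `"pso"`.
#' @param pop,iters Population size and iteration count.
#' @param k CV folds for the fitness.
#' @param space Optional [search_space()]; defaults to the algorithm's
#'   standard (c, g) ranges.
#' @param seed Integer seed (optimizer and CV folds).
#' @return An `opt_result` whose `best` holds the tuned `c` and `g`.
#' @export
tune_svm <- function(table, algorithm = c("gwo", "ga", "pso"), pop = 20L,
                     iters = 100L, k = 5L, space = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  space <- space %||% default_space(algorithm)
  xy <- as_xy_class(table)
  cv_seed <- derive_seed(seed, "cv-folds")
  cache <- new.env(parent = emptyenv())
  fitness <- function(th) {
    key <- paste(signif(th, 6), collapse = "|")
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    val <- cv_accuracy(xy$x, xy$y, cost = th[1], gamma = th[2], k = k,
                       seed = cv_seed)
    assign(key, val, envir = cache)
    val
  }
  opt_seed <- derive_seed(seed, paste0("tune-", algorithm))
  switch(algorithm,
         gwo = gwo(fitness, space, pop, iters, seed = opt_seed),
         ga  = ga(fitness, space, pop, iters, seed = opt_seed),
         pso = pso(fitness, space, pop, iters, seed = opt_seed))
}
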