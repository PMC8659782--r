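sphere <- function(th) -(th[1] - 3)^2 - (th[2] - 1)^2
box <- search_space(c(x = 0.01, y = 0.01), c(x = 5, y = 5))

# multimodal ripple with global maximum 1 at (3, 3) and local peaks on the
# unit grid around it
ripple <- function(th) {
  -((th[1] - 3)^2 + (th[2] - 3)^2) / 2 +
    0.5 * cos(2 * pi * (th[1] - 3)) + 0.5 * cos(2 * pi * (th[2] - 3))
}
ripple_box <- search_space(c(x = 0.1, y = 0.1), c(x = 6, y = 6))

test_that("all three optimizers locate a quadratic optimum", {
  g <- gwo(sphere, box, pop = 20, iters = 100, seed = 1)
  expect_lt(max(abs(g$best - c(3, 1))), 0.05)
  a <- ga(sphere, box, pop = 20, iters = 100, seed = 1)
  expect_lt(max(abs(a$best - c(3, 1))), 0.1)
  p <- pso(sphere, box, pop = 20, iters = 100, seed = 1)
  expect_lt(max(abs(p$best - c(3, 1))), 0.1)
})

test_that("best-so-far traces are monotone and reproducible", {
  for (f in list(gwo, ga, pso)) {
    r1 <- f(sphere, box, pop = 20, iters = 30, seed = 5)
    expect_true(all(diff(r1$trace$best_fitness) >= 0))
    expect_equal(r1$best_fitness,
                 r1$trace$best_fitness[nrow(r1$trace)])
    r2 <- f(sphere, box, pop = 20, iters = 30, seed = 5)
    expect_identical(r1$trace, r2$trace)
    expect_identical(r1$best, r2$best)
  }
})

test_that("every evaluated candidate respects the declared bounds", {
  seen <- list()
  spy <- function(th) {
    seen[[length(seen) + 1]] <<- th
    sphere(th)
  }
  for (f in list(gwo, ga, pso)) {
    seen <- list()
    f(spy, box, pop = 10, iters = 20, seed = 3)
    pts <- do.call(rbind, seen)
    expect_true(all(pts[, 1] >= box$lower[1] - 1e-12 &
                      pts[, 1] <= box$upper[1] + 1e-12))
    expect_true(all(pts[, 2] >= box$lower[2] - 1e-12 &
                      pts[, 2] <= box$upper[2] + 1e-12))
  }
})

test_that("one GWO step never loses the initial population's best", {
  r <- gwo(sphere, box, pop = 3, iters = 1, seed = 9)
  expect_gte(r$best_fitness, r$trace$best_fitness[1])
})

test_that("elitist GA without variation never degrades", {
  r <- ga(sphere, box, pop = 10, iters = 25, p_cross = 0, p_mut = 0, seed = 2)
  expect_true(all(diff(r$trace$best_fitness) >= 0))
})

test_that("a non-finite fitness discards the candidate with a warning", {
  bad <- function(th) if (th[1] > 2.5) NaN else sphere(th)
  expect_warning(r <- gwo(bad, box, pop = 10, iters = 5, seed = 4),
                 "non-finite")
  expect_true(is.finite(r$best_fitness))
})

test_that("optimizers find a multimodal global basin in most seeded runs", {
  hits <- sapply(list(gwo = gwo, ga = ga, pso = pso), function(f) {
    sum(sapply(1:10, function(s)
      f(ripple, ripple_box, pop = 20, iters = 100, seed = s)$best_fitness >=
        0.99))
  })
  expect_true(all(hits >= 9))
})

test_that("svm tuning echoes paper defaults and improves on untuned fits", {
  tab <- planted_fixture(seed = 19, n_samples = 120, n_informative = 3,
                         n_noise = 3, noise_sd = 0.8)
  expect_equal(formals(tune_svm)$pop, 20L)
  expect_equal(formals(tune_svm)$iters, 100L)
  sp <- stratified_split(tab, 0.7, seed = 1)
  tuned <- tune_svm(sp$train, "gwo", pop = 8, iters = 12, seed = 1)
  base <- train_svm(sp$train, cost = 1)
  opt <- train_svm(sp$train, cost = tuned$best[["c"]],
                   gamma = tuned$best[["g"]])
  expect_gte(evaluate(opt, sp$test)$accuracy,
             evaluate(base, sp$test)$accuracy)
  tuned2 <- tune_svm(sp$train, "gwo", pop = 8, iters = 12, seed = 1)
  expect_identical(tuned$best, tuned2$best)
  expect_s3_class(autoplot(tuned), "ggplot")
  gl <- glance(tuned)
  expect_equal(gl$best_fitness, tuned$best_fitness)
})

test_that("default search ranges follow each algorithm's convention", {
  expect_equal(rootgrader:::default_space("gwo")$upper, c(100, 100))
  expect_equal(rootgrader:::default_space("ga")$upper, c(100, 1000))
  expect_equal(rootgrader:::default_space("pso")$lower, c(0.1, 0.01))
  expect_error(search_space(c(0, 1), c(2, 3)), "positive")
  expect_error(search_space(c(2, 1), c(1, 3)), "lower")
})
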