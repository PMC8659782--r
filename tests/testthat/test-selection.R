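test_that("rmsecv behaves like a cross-validated error", {
  tab0 <- planted_fixture(seed = 3, n_samples = 80, n_informative = 3,
                          n_noise = 2, noise_sd = 0)
  # noiseless planted signal: held-out error is essentially zero
  expect_lt(rmsecv(as.matrix(tab0[attr(tab0, "informative")]), tab0$grade),
            0.1)
  tab <- planted_fixture(seed = 4, n_samples = 60, n_informative = 2,
                         n_noise = 3)
  s1 <- rmsecv(tab, seed = 9)
  expect_gte(s1, 0)
  expect_identical(s1, rmsecv(tab, seed = 9))
  expect_error(rmsecv(tab[1:4, ], k = 5), "fewer rows")
})

test_that("a single informative feature survives IRIV", {
  tab <- planted_fixture(seed = 5, n_samples = 80, n_informative = 1,
                         n_noise = 6, noise_sd = 0.3)
  sel <- iriv_select(tab, seed = 2)
  expect_true("inf_1" %in% sel$selected)
})

test_that("IRIV recovers planted signal and controls noise", {
  hits <- sapply(1:3, function(s) {
    tab <- planted_fixture(seed = s + 40)
    sel <- iriv_select(tab, seed = s)
    inf <- attr(tab, "informative")
    c(inf = sum(sel$selected %in% inf),
      noise = sum(!sel$selected %in% inf))
  })
  expect_true(all(hits["inf", ] >= 4))
  expect_true(all(hits["noise", ] <= 3))
})

test_that("IRIV classification history uses the four sensitivity categories", {
  tab <- planted_fixture(seed = 44)
  sel <- iriv_select(tab, seed = 4)
  expect_true(all(sel$classification$category %in%
                    c("strong", "weak", "uninformative", "interfering")))
  inf <- attr(tab, "informative")
  first <- sel$classification[sel$classification$round == 1, ]
  expect_true(all(first$category[first$variable %in% inf] %in%
                    c("strong", "weak")))
})

test_that("IRIV elimination trace is monotone non-increasing", {
  tab <- planted_fixture(seed = 46)
  sel <- iriv_select(tab, seed = 6)
  elim <- sel$trace$rmsecv[sel$trace$phase == "elimination"]
  expect_true(all(diff(elim) <= 1e-12))
})

test_that("selected subsets never score worse than the full table", {
  for (s in 1:2) {
    tab <- planted_fixture(seed = s + 50)
    full <- rmsecv(tab, seed = 77)
    for (sel in list(iriv_select(tab, seed = s), vissa_select(tab, seed = s))) {
      sub <- rmsecv(as.matrix(tab[sel$selected]), tab$grade, seed = 77)
      expect_lte(sub, full)
    }
  }
})

test_that("VISSA pins a noiseless single informative feature at weight one", {
  tab <- planted_fixture(seed = 61, n_samples = 80, n_informative = 1,
                         n_noise = 4, noise_sd = 0)
  sel <- vissa_select(tab, seed = 1)
  expect_true("inf_1" %in% sel$selected)
  w_final <- sel$weights[sel$weights$iteration == max(sel$weights$iteration), ]
  expect_equal(w_final$weight[w_final$variable == "inf_1"], 1)
})

test_that("VISSA recovers the planted informative features", {
  hits <- sapply(1:3, function(s) {
    tab <- planted_fixture(seed = s + 60)
    sel <- vissa_select(tab, seed = s)
    sum(sel$selected %in% attr(tab, "informative"))
  })
  expect_true(all(hits >= 4))
})

test_that("the VISSA ranking curve falls to a minimum then rises", {
  tab <- planted_fixture(seed = 63)
  sel <- vissa_select(tab, seed = 3)
  rk <- sel$trace[sel$trace$phase == "ranking", ]
  k_best <- which.min(rk$rmsecv)
  expect_gt(k_best, 1)
  # strictly better than tiny models and no better value beyond it
  expect_lt(rk$rmsecv[k_best], rk$rmsecv[1])
  expect_true(all(rk$rmsecv[-seq_len(k_best)] >= rk$rmsecv[k_best]))
})

test_that("stepwise regression isolates the true predictor", {
  withr::with_seed(71, {
    x1 <- rnorm(100)
    x2 <- rnorm(100)
    y <- 2 * x1 + rnorm(100, 0, 0.1)
    tab <- tibble::tibble(x1 = x1, x2 = x2, grade = y)
  })
  sel <- sra_select(tab)
  expect_identical(sel$selected, "x1")
})

test_that("stepwise regression skips degenerate and duplicate columns", {
  tab0 <- planted_fixture(seed = 72, n_samples = 80, n_informative = 2,
                          n_noise = 2, noise_sd = 0)
  tab0$flat <- 1            # zero variance
  tab0$dup <- tab0$inf_1    # exact collinear duplicate
  sel <- sra_select(tab0)
  expect_false("flat" %in% sel$selected)
  expect_false(all(c("inf_1", "dup") %in% sel$selected))
  # noiseless construction: the selected set reproduces the labels
  fit <- lm(as.integer(tab0$grade) ~ ., data = tab0[sel$selected])
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("pure-noise tables yield at most 10% selections or a warning", {
  for (s in 1:3) {
    tab <- planted_fixture(seed = s + 80, n_samples = 120, n_informative = 0,
                           n_noise = 40, noise_sd = 0)
    for (f in list(iriv_select, vissa_select)) {
      sel <- suppressWarnings(f(tab, seed = s))
      expect_lte(length(sel$selected), 4)
    }
    sel <- suppressWarnings(sra_select(tab))
    expect_lte(length(sel$selected), 4)
  }
})

test_that("selection is reproducible under a fixed seed", {
  tab <- planted_fixture(seed = 90, n_samples = 100, n_informative = 3,
                         n_noise = 10)
  a <- iriv_select(tab, seed = 7)
  b <- iriv_select(tab, seed = 7)
  expect_identical(a$selected, b$selected)
  expect_identical(a$trace, b$trace)
  va <- vissa_select(tab, seed = 7)
  vb <- vissa_select(tab, seed = 7)
  expect_identical(va$selected, vb$selected)
})

test_that("selection results expose tidy, glance and autoplot", {
  tab <- planted_fixture(seed = 91, n_samples = 80, n_informative = 2,
                         n_noise = 5)
  sel <- sra_select(tab)
  expect_s3_class(tidy(sel), "tbl_df")
  gl <- glance(sel)
  expect_equal(gl$n_selected, length(sel$selected))
  expect_s3_class(autoplot(sel), "ggplot")
})
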