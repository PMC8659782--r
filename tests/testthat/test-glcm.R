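test_that("co-occurrence counts of a hand-enumerated row are exact", {
  g <- matrix(c(0, 0, 255, 255), nrow = 1)
  m <- compute_glcm(g, d = 1, theta = 0, levels = 2)
  # symmetric pairs (0,0):2, (0,1):2 split across orders, (1,1):2 -> 1/3 each
  expect_equal(m[1, 1], 1 / 3)
  expect_equal(m[1, 2] + m[2, 1], 1 / 3)
  expect_equal(m[2, 2], 1 / 3)
})

test_that("a constant image concentrates all mass on one diagonal cell", {
  m <- compute_glcm(matrix(100, 8, 8), d = 2, theta = 45, levels = 64)
  expect_equal(sum(m), 1)
  expect_equal(max(diag(unclass(m))), 1)
})

test_that("co-occurrence matrices are symmetric probability matrices", {
  withr::with_seed(5, {
    for (th in c(0, 45, 90, 135)) {
      g <- matrix(sample(0:255, 20 * 20, replace = TRUE), 20)
      m <- unclass(compute_glcm(g, d = 2, theta = th, levels = 16))
      expect_equal(sum(m), 1)
      expect_equal(m, t(m))
    }
  })
})

test_that("glcm construction matches the pair-enumeration oracle", {
  withr::with_seed(17, {
    for (i in 1:20) {
      g <- matrix(sample(0:255, 15 * 15, replace = TRUE), 15)
      mask <- matrix(rbinom(225, 1, 0.8), 15, 15)
      th <- sample(c(0, 45, 90, 135), 1)
      got <- tryCatch(unclass(compute_glcm(g, mask, d = 2, theta = th,
                                           levels = 8)),
                      error = function(e) NULL)
      if (is.null(got)) next
      expect_equal(got, oracle_glcm(g, mask, 2, th, 8), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  })
})

test_that("texture statistics of the two-cell worked example are exact", {
  f <- matrix(0, 2, 2)
  f[1, 1] <- f[2, 2] <- 0.5
  feats <- glcm_features(f)
  expect_equal(feats$Homogeneity, 1)
  expect_equal(feats$Contrast, 0)
  expect_equal(feats$Dissimilarity, 0)
  expect_equal(feats$Energy, 0.5)
  expect_equal(feats$Entropy, log10(2))
  expect_equal(feats$Auto_Correlation, 0.5)
  expect_equal(feats$Correlation, 1)  # all mass on the diagonal
})

test_that("a single-entry matrix has unit energy and zero entropy", {
  f <- matrix(0, 4, 4)
  f[2, 2] <- 1
  feats <- glcm_features(f)
  expect_equal(feats$Energy, 1)
  expect_equal(feats$Entropy, 0)
  expect_equal(feats$Contrast, 0)
  expect_equal(feats$Homogeneity, 1)
})

test_that("texture statistics match the double-loop oracle", {
  withr::with_seed(23, {
    for (i in 1:20) {
      L <- sample(c(4, 8, 16), 1)
      raw <- matrix(runif(L * L), L, L)
      f <- (raw + t(raw))
      f <- f / sum(f)
      got <- unlist(glcm_features(f))
      expect_equal(got, oracle_glcm_features(f), tolerance = 1e-9)
    }
  })
})

test_that("direction-averaged features have the expected symmetries", {
  cm <- extract_texture_features(matrix(77, 32, 32),
                                 matrix(1, 32, 32))
  expect_equal(cm$Energy, 1)
  expect_equal(cm$Contrast, 0)

  withr::with_seed(29, {
    g <- matrix(sample(0:255, 48 * 48, replace = TRUE), 48)
    m <- matrix(1, 48, 48)
    a <- extract_texture_features(g, m)
    # rotating by 90 degrees permutes the direction set
    b <- extract_texture_features(t(g[nrow(g):1, ]), m)
    expect_equal(a, b, tolerance = 1e-6)
  })
})

test_that("per-direction contrast of isotropic noise is stable within 20%", {
  withr::with_seed(37, {
    g <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64)
    m <- matrix(1, 64, 64)
    per_dir <- sapply(c(0, 45, 90, 135), function(th)
      glcm_features(compute_glcm(g, m, d = 2, theta = th, levels = 64))$Contrast)
    expect_true(all(abs(per_dir - mean(per_dir)) / mean(per_dir) < 0.2))
  })
})

test_that("degenerate masks raise texture errors", {
  expect_error(compute_glcm(matrix(9, 4, 4), matrix(0, 4, 4), d = 1,
                            theta = 0, levels = 4), "degenerate")
  mask <- matrix(0, 10, 10)
  mask[5, 5] <- 1  # single pixel: no pair at any offset
  expect_error(extract_texture_features(matrix(9, 10, 10), mask),
               "degenerate")
})

test_that("windowed texture extraction averages over tiles", {
  withr::with_seed(41, {
    g <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64)
    m <- matrix(0, 64, 64)
    m[10:55, 10:55] <- 1
    f <- extract_texture_features(g, m, window = 16)
    expect_true(all(is.finite(unlist(f))))
    expect_equal(names(f), feature_names("texture"))
  })
})
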