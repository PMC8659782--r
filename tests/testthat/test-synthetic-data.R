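test_that("root image generation is a pure function of spec, grade, seed", {
  spec <- small_image_spec()
  a <- generate_root_image(spec, "I", seed = 1)
  b <- generate_root_image(spec, "I", seed = 1)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$weight_g, b$weight_g)
  d <- generate_root_image(spec, "I", seed = 2)
  expect_false(identical(a$image, d$image))
})

test_that("generated weight matches the requested grade", {
  spec <- small_image_spec()
  for (g in c("I", "II", "III", "IV")) {
    r <- generate_root_image(spec, g, seed = 5)
    expect_equal(as.character(assign_grade(r$weight_g)), g)
  }
})

test_that("mean foreground area is ordered grade I > II > III > IV", {
  spec <- small_image_spec()
  areas <- sapply(c("I", "II", "III", "IV"), function(g)
    mean(sapply(1:50, function(s)
      sum(generate_root_image(spec, g, seed = s)$mask))))
  expect_true(all(diff(areas) < 0))
})

test_that("ground-truth mask agrees with the Otsu pipeline mask", {
  spec <- synthetic_image_spec(canvas = 256)
  for (s in 1:3) {
    r <- generate_root_image(spec, sample(c("I", "IV"), 1), seed = s)
    pre <- preprocess(r$image, list(resize_to = c(256, 256)))
    expect_gt(jaccard(pre$mask, r$mask), 0.9)
  }
})

test_that("a blob larger than the canvas is rejected", {
  spec <- small_image_spec()
  spec$major_mean <- spec$canvas * c(1.2, 1.1, 1.05, 1.0)
  expect_error(generate_root_image(spec, "I", seed = 1), "canvas")
})

test_that("image datasets are balanced, sized and reproducible", {
  spec <- small_image_spec()
  ds <- generate_image_dataset(spec, n_per_grade = 2, seed = 3)
  expect_equal(nrow(ds), 8L)
  expect_equal(as.integer(table(ds$grade)), rep(2L, 4))
  ds2 <- generate_image_dataset(spec, n_per_grade = 2, seed = 3)
  expect_identical(ds$grade, ds2$grade)
  expect_identical(ds$image[[5]], ds2$image[[5]])
  expect_error(generate_image_dataset(spec, 0), ">= 1")
})

test_that("image datasets round-trip through PNG plus manifest", {
  spec <- small_image_spec()
  ds <- generate_image_dataset(spec, n_per_grade = 1, seed = 9)
  dir <- withr::local_tempdir()
  write_image_dataset(ds, dir)
  back <- read_image_dataset(dir)
  expect_equal(nrow(back), 4L)
  expect_identical(back$grade, ds$grade)
  expect_equal(back$image[[2]], ds$image[[2]])
  expect_equal(back$mask[[3]], ds$mask[[3]])
})

test_that("planted tables are deterministic with planted-signal structure", {
  spec <- planted_table_spec(n_samples = 60, n_informative = 3, n_noise = 4,
                             noise_sd = 0, seed = 21)
  tab <- generate_feature_table(spec)
  expect_identical(tab, generate_feature_table(spec))
  expect_equal(attr(tab, "informative"), c("inf_1", "inf_2", "inf_3"))
  # noiseless construction: a linear fit on any informative column is exact
  y <- as.integer(tab$grade)
  fit <- lm(y ~ inf_1, data = tab)
  expect_lt(max(abs(residuals(fit))), 1e-9)
})

test_that("informative columns carry the label signal, noise columns do not", {
  tab <- planted_fixture(seed = 7, n_samples = 200, n_informative = 5,
                         n_noise = 35)
  inf <- attr(tab, "informative")
  noise <- setdiff(setdiff(names(tab), c("sample_id", "grade")), inf)
  y <- tab$grade
  r_inf <- rmsecv(as.matrix(tab[inf]), y, seed = 1)
  r_noise <- rmsecv(as.matrix(tab[noise]), y, seed = 1)
  expect_lt(r_inf, r_noise)
})

test_that("planted-table spec validates its invariants", {
  expect_error(planted_table_spec(n_samples = 10), "at least 4 x")
  expect_error(planted_table_spec(n_informative = 0, n_noise = 0))
})
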