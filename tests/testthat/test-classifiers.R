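test_that("stratified splitting preserves class balance at the 7:3 ratio", {
  big <- tibble::tibble(
    x = rnorm(1800),
    grade = factor(rep(c("I", "II", "III", "IV"), each = 450),
                   levels = c("I", "II", "III", "IV")))
  sp <- stratified_split(big, 0.7, seed = 1)
  expect_equal(nrow(sp$train), 1260L)
  expect_equal(nrow(sp$test), 540L)
  expect_equal(as.integer(table(sp$train$grade)), rep(315L, 4))
  expect_equal(as.integer(table(sp$test$grade)), rep(135L, 4))

  ten <- tibble::tibble(x = rnorm(10),
                        grade = factor(rep("I", 10),
                                       levels = c("I", "II", "III", "IV")))
  sp10 <- stratified_split(ten, 0.7, seed = 2)
  expect_equal(nrow(sp10$train), 7L)
  expect_equal(nrow(sp10$test), 3L)

  sp2 <- stratified_split(big, 0.7, seed = 1)
  expect_identical(sp$train$x, sp2$train$x)
  expect_error(stratified_split(big, 1.2), "in \\(0, 1\\)")
})

test_that("the RBF-SVM separates well-separated blobs and shatters XOR", {
  tab <- blob_table(n_per_class = 50, seed = 2)
  m <- train_svm(tab, cost = 1)
  expect_equal(evaluate(m, tab)$accuracy, 100)

  xor <- withr::with_seed(3, tibble::tibble(
    x1 = rep(c(0, 1, 0, 1), each = 25) + rnorm(100, 0, 0.05),
    x2 = rep(c(0, 1, 1, 0), each = 25) + rnorm(100, 0, 0.05),
    grade = factor(rep(c("I", "I", "II", "II"), each = 25),
                   levels = c("I", "II", "III", "IV"))))
  mx <- train_svm(xor, cost = 10, gamma = 1)
  expect_equal(evaluate(mx, xor)$accuracy, 100)
})

test_that("a vanishing penalty collapses the SVM to the majority rate", {
  tab <- withr::with_seed(5, tibble::tibble(
    x1 = c(rnorm(75, 1.5), rnorm(25, -1.5)),
    x2 = rnorm(100),
    grade = factor(rep(c("I", "II"), c(75, 25)),
                   levels = c("I", "II", "III", "IV"))))
  strong <- evaluate(train_svm(tab, cost = 10), tab)$accuracy
  weak <- evaluate(train_svm(tab, cost = 1e-4), tab)$accuracy
  expect_equal(weak, 75)  # the 75/25 majority rate
  expect_gt(strong, weak)
  expect_error(train_svm(tab, cost = 0), "> 0")
  one <- tab[tab$grade == "I", ]
  expect_error(train_svm(one), "2 classes")
})

test_that("the ELM interpolates with enough hidden units and is seeded", {
  tab <- withr::with_seed(7, tibble::tibble(
    x1 = rnorm(50), x2 = rnorm(50), x3 = rnorm(50),
    grade = factor(sample(c("I", "II", "III", "IV"), 50, replace = TRUE),
                   levels = c("I", "II", "III", "IV"))))
  big <- train_elm(tab, n_hidden = 80, seed = 1)
  expect_gte(evaluate(big, tab)$accuracy, 98)
  expect_identical(train_elm(tab, n_hidden = 80, seed = 1)$fit$beta,
                   big$fit$beta)
  small <- train_elm(tab, n_hidden = 1, seed = 1)
  expect_lt(evaluate(small, tab)$accuracy, evaluate(big, tab)$accuracy - 20)
})

test_that("the BP network learns separable data and is reproducible", {
  tab <- blob_table(n_per_class = 40, sep = 4, seed = 9)
  m <- train_bp(tab, epochs = 500, seed = 1)
  expect_gte(evaluate(m, tab)$accuracy, 95)
  m2 <- train_bp(tab, epochs = 500, seed = 1)
  expect_identical(m$fit$w1, m2$fit$w1)

  zero <- train_bp(tab, epochs = 0, seed = 3)
  acc0 <- evaluate(zero, tab)$accuracy
  expect_lt(abs(acc0 - 50), 10.0001)  # balanced 2-class chance

  expect_error(train_bp(tab, learning_rate = 1e8, epochs = 200, seed = 1),
               "learning_rate")
})

test_that("evaluation reports are conserved and consistent", {
  tab <- blob_table(n_per_class = 30, classes = c("I", "II", "III", "IV"),
                    sep = 4, seed = 11)
  m <- train_svm(tab, cost = 10)
  rep <- evaluate(m, tab)
  expect_equal(sum(rep$confusion), nrow(tab))
  expect_equal(rep$accuracy, 100 * sum(diag(rep$confusion)) / rep$n)
  expect_equal(as.integer(rowSums(rep$confusion)),
               as.integer(table(tab$grade)))
  expect_equal(rep$macro_accuracy, mean(rep$per_class))
  expect_equal(sum(tidy(rep)$count), rep$n)
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("svm predictions are invariant to consistent column permutation", {
  tab <- planted_fixture(seed = 13, n_samples = 80, n_informative = 3,
                         n_noise = 5)
  X <- as.matrix(tab[, setdiff(names(tab), c("sample_id", "grade"))])
  y <- tab$grade
  perm <- rev(seq_len(ncol(X)))
  m1 <- train_svm(X, y, cost = 2, gamma = 0.1)
  m2 <- train_svm(X[, perm], y, cost = 2, gamma = 0.1)
  expect_equal(predict(m1, X), predict(m2, X[, perm]))
})

test_that("cross-validated accuracy is high when separable, chance when not", {
  tab <- blob_table(n_per_class = 50, classes = c("I", "II", "III", "IV"),
                    sep = 4, seed = 15)
  X <- as.matrix(tab[, c("x1", "x2")])
  expect_gte(cv_accuracy(X, tab$grade, cost = 10, seed = 1), 95)
  Xnull <- withr::with_seed(15, cbind(rnorm(300), rnorm(300)))
  ynull <- factor(rep(c("I", "II", "III", "IV"), length.out = 300),
                  levels = c("I", "II", "III", "IV"))
  ynull <- withr::with_seed(16, sample(ynull))
  acc_null <- cv_accuracy(Xnull, ynull, cost = 1, seed = 1)
  expect_lt(abs(acc_null - 25), 7.0001)
  expect_identical(cv_accuracy(X, tab$grade, cost = 10, seed = 4),
                   cv_accuracy(X, tab$grade, cost = 10, seed = 4))
})

test_that("evaluation rejects labels never seen in training", {
  two <- blob_table(n_per_class = 20, seed = 17)
  m <- train_svm(two, cost = 1)
  four <- blob_table(n_per_class = 5, classes = c("I", "II", "III"), seed = 18)
  expect_error(evaluate(m, four), "outside the training label set")
})
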