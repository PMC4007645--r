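test_that("kNN classification follows the documented vote and tie rules", {
  train <- matrix(c(0, 1, 2, 3, 4, 10), ncol = 1)
  labels <- c("A", "A", "A", "B", "B", "B")
  ## query at 1.5: five nearest are rows 1-5, labels A,A,A,B,B -> A
  expect_equal(knn_classify(train, labels, matrix(1.5), k = 5), "A")
  ## query identical to a training point with k = 1
  expect_equal(knn_classify(train, labels, matrix(10), k = 1), "B")
  ## k larger than the training set errors
  expect_error(knn_classify(train, labels, matrix(0), k = 7))
})

test_that("3-class vote ties go to the nearest neighbour, verified exhaustively", {
  ## one query with three equidistant-by-class neighbours at k = 3
  train <- matrix(c(1, 2, 3), ncol = 1)
  labels <- c("A", "B", "C")
  for (q in seq(0.1, 3.9, by = 0.2)) {
    pred <- knn_classify(train, labels, matrix(q), k = 3)
    d <- abs(train[, 1] - q)
    nearest <- order(d)[1]  # stable: smaller index wins distance ties
    expect_equal(pred, labels[nearest])
  }
})

test_that("LOOCV accuracy agrees with the brute-force oracle", {
  set.seed(30)
  for (i in 1:5) {
    x <- matrix(rnorm(24), 12, 2)
    labels <- rep(c("A", "B"), each = 6)
    expect_equal(loocv_accuracy(x, labels, k = 3),
                 oracle_loocv(x, labels, k = 3))
  }
  ## tight separated clouds are perfectly classified
  x <- rbind(matrix(rnorm(10, 0, 0.01), 5, 2),
             matrix(rnorm(10, 5, 0.01), 5, 2))
  expect_equal(loocv_accuracy(x, rep(c("A", "B"), each = 5), k = 3), 1)
  ## constant feature: all points identical, ties resolved by index;
  ## the oracle defines the expected value
  x0 <- matrix(0, 6, 1)
  lab0 <- c("A", "B", "A", "B", "A", "B")
  expect_equal(loocv_accuracy(x0, lab0, k = 3),
               oracle_loocv(x0, lab0, k = 3))
})

test_that("permuted labels give chance-level LOOCV", {
  set.seed(31)
  x <- matrix(rnorm(80), 40, 2)
  accs <- replicate(50, loocv_accuracy(x, sample(rep(c("A", "B"), 20)),
                                       k = 5))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("random-kNN ensembles are reproducible and cover features binomially", {
  set.seed(32)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  labels <- rep(c("A", "B"), 5)
  m1 <- fit_rknn(x, labels, r = 50, m = 2, k = 3, seed = 9)
  m2 <- fit_rknn(x, labels, r = 50, m = 2, k = 3, seed = 9)
  expect_identical(m1$subsets, m2$subsets)
  expect_identical(m1$accuracies, m2$accuracies)
  ## m = p: every base model scores the full feature set
  full <- fit_rknn(x, labels, r = 3, m = 4, k = 3, seed = 10)
  expect_true(all(full$accuracies == loocv_accuracy(x, labels, k = 3)))
  ## coverage concentrates around r * m / p
  big <- fit_rknn(x, labels, r = 1000, m = 2, k = 3, seed = 11)
  cov <- feature_support(big)$coverage
  expect_true(all(abs(cov - 500) <= 3 * sqrt(500)))
})

test_that("support equals the exhaustive subset average exactly", {
  set.seed(33)
  x <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("f", 1:6)))
  labels <- rep(c("A", "B"), each = 5)
  for (m in 2:3) {
    subsets <- utils::combn(6, m, simplify = FALSE)
    model <- fit_rknn(x, labels, r = length(subsets), m = m, k = 3,
                      subsets = subsets)
    supp <- feature_support(model)
    ## brute force with the independent oracle
    for (f in 1:6) {
      keep <- vapply(subsets, function(s) f %in% s, logical(1))
      expected <- mean(vapply(subsets[keep], function(s)
        oracle_loocv(x[, s, drop = FALSE], labels, k = 3), numeric(1)))
      expect_equal(supp$support[supp$feature == paste0("f", f)], expected)
    }
  }
})

test_that("a single perfectly separating feature reaches support 1 exactly", {
  set.seed(34)
  x <- cbind(f1 = c(rep(0, 10), rep(10, 10)) + rnorm(20, 0, 0.01),
             f2 = rnorm(20), f3 = rnorm(20), f4 = rnorm(20))
  labels <- rep(c("A", "B"), each = 10)
  model <- fit_rknn(x, labels, r = 300, m = 1, k = 5, seed = 12)
  supp <- feature_support(model)
  expect_equal(supp$support[supp$feature == "f1"], 1.0)
  ## pure-noise features stay clearly below 1 at this sample size
  noise_supp <- supp$support[supp$feature != "f1"]
  expect_true(all(noise_supp < 0.9, na.rm = TRUE))
  ## constant base accuracy implies constant support
  flat <- model
  flat$accuracies <- rep(0.7, flat$r)
  fs <- feature_support(flat)
  expect_true(all(abs(fs$support[fs$coverage > 0] - 0.7) < 1e-12))
})

test_that("geometric elimination follows the ceiling schedule and degenerate
           n_select keeps the whole winning stage", {
  set.seed(35)
  x <- matrix(rnorm(160), 20, 8, dimnames = list(NULL, paste0("f", 1:8)))
  labels <- rep(c("A", "B"), 10)
  rk <- geometric_backward_elimination(x, labels, r = 30, k = 3,
                                       keep_ratio = 0.5, floor_features = 2,
                                       n_select = 30, seed = 13)
  expect_equal(rk$path$n_features, c(8, 4, 2))
  ## n_select >= p: the winning stage's whole feature set is selected
  expect_setequal(rk$selected,
                  rk$support$feature)
  expect_true(all(diff(rk$path$n_features) < 0))
})

test_that("the elimination path is reproducible from data, params and seed", {
  set.seed(36)
  x <- matrix(rnorm(300), 20, 15, dimnames = list(NULL, paste0("f", 1:15)))
  labels <- rep(c("A", "B"), 10)
  a <- geometric_backward_elimination(x, labels, r = 40, k = 3,
                                      floor_features = 4, n_select = 5,
                                      seed = 14)
  b <- geometric_backward_elimination(x, labels, r = 40, k = 3,
                                      floor_features = 4, n_select = 5,
                                      seed = 14)
  expect_identical(a$path, b$path)
  expect_identical(a$selected, b$selected)
  expect_identical(a$loocv_accuracy, b$loocv_accuracy)
})
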