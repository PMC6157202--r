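test_that("separable clouds are learned perfectly by a linear SVM", {
  tab <- gauss_table(c(lo = -5, hi = 5), n_per_class = 50, k = 2,
                     sd = 0.1)
  fit <- train_svm(tab, kernel_spec("linear"))
  pred <- predict(fit, tab)
  expect_equal(mean(as.character(pred) == tab$label), 1.0)
})

test_that("XOR layout defeats the linear kernel but not the quadratic", {
  tab <- xor_table()
  lin <- train_svm(tab, kernel_spec("linear"))
  acc_lin <- mean(as.character(predict(lin, tab)) == tab$label)
  expect_lte(acc_lin, 0.75)
  quad <- train_svm(tab, kernel_by_name("quadratic"))
  acc_quad <- mean(as.character(predict(quad, tab)) == tab$label)
  expect_equal(acc_quad, 1.0)
})

test_that("degenerate classification inputs are rejected", {
  tab <- gauss_table(c(only = 0), n_per_class = 10, k = 2)
  expect_error(train_svm(tab), "2 classes")
  expect_error(kernel_spec("linear", degree = 2), "degree 1")
  expect_error(kernel_spec("polynomial", degree = 4), "1, 2 or 3")
  small <- gauss_table(c(A = 0, B = 3), n_per_class = 3)
  expect_error(cross_validate(small, n_folds = 5), "at least n_folds")
})

test_that("fold assignment is a stratified partition, reproducible", {
  y <- factor(rep(c("a", "b", "c"), each = 100))
  f1 <- assign_folds(y, 5, seed = 3)
  f2 <- assign_folds(y, 5, seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, assign_folds(y, 5, seed = 4)))
  # every row in exactly one fold; 20 per class per fold
  expect_equal(sort(unique(f1)), 1:5)
  expect_true(all(table(y, f1) == 20))
})

test_that("cross-validation is deterministic and accurate when separable", {
  tab <- gauss_table(c(A = -4, B = 0, C = 4), n_per_class = 20, k = 3,
                     sd = 0.3)
  cv1 <- cross_validate(tab, kernel_spec("linear"), seed = 0)
  cv2 <- cross_validate(tab, kernel_spec("linear"), seed = 0)
  expect_identical(cv1$fold_accuracies, cv2$fold_accuracies)
  expect_equal(cv1$mean_accuracy, 1.0)
  expect_equal(cv1$mean_accuracy, mean(cv1$fold_accuracies),
               tolerance = 1e-12)
  # pooled confusion matrix accounts for every row once
  expect_equal(rowSums(cv1$confusion), c(A = 20, B = 20, C = 20))
})

test_that("standardization statistics never depend on the test fold", {
  tab <- gauss_table(c(A = 0, B = 2), n_per_class = 25, k = 3, sd = 1)
  y <- factor(tab$label)
  folds <- assign_folds(y, 5, seed = 1)
  X <- feature_matrix(tab)
  tr <- folds != 1
  base <- msldSampEn:::.fit_scaler(X[tr, , drop = FALSE])
  X2 <- X
  X2[!tr, ] <- X2[!tr, ] * 1000 + 77   # perturb the held-out fold only
  after <- msldSampEn:::.fit_scaler(X2[tr, , drop = FALSE])
  expect_identical(base, after)
})

test_that("label-permuted data scores at chance level", {
  tab <- gauss_table(c(A = 0, B = 2, C = 4), n_per_class = 20, k = 3,
                     sd = 0.5)
  n <- nrow(tab)
  accs <- vapply(1:20, function(s) {
    ptab <- tab
    ptab$label <- withr::with_seed(1000 + s, sample(tab$label))
    cross_validate(ptab, kernel_spec("linear"), seed = s)$mean_accuracy
  }, numeric(1))
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(mean(accs) - 1 / 3), 3 * se)
})

test_that("accuracy_grid fills every (r, range, kernel) cell", {
  set <- gen_labeled_set(n_per_class = 6, n_samples = 192, seed = 5)
  grid <- accuracy_grid(set,
                        kernels = list(kernel_spec("linear"),
                                       kernel_by_name("cubic")),
                        r_values = c(0.2, 0.25),
                        scale_ranges = list(c(1, 6), c(1, 3)),
                        n_folds = 3, seed = 0)
  expect_named(grid$cells, c("linear", "cubic"))
  for (cells in grid$cells) {
    expect_equal(dim(cells), c(2, 2))
    expect_true(all(cells >= 0 & cells <= 100))
  }
  # restricted ranges are column slices of one wide extraction, so the
  # wide-range cell must equal a direct run at the wide range
  direct <- cross_validate(
    extract_feature_table(set, 1, 6, sampen_params(m = 2, r = 0.2)),
    kernel_spec("linear"), n_folds = 3, seed = 0)
  expect_equal(grid$cells$linear["r=0.2", "1-6"],
               round(100 * direct$mean_accuracy, 1))

  empty <- accuracy_grid(set, kernels = list(), r_values = 0.25,
                         scale_ranges = list(c(1, 3)), n_folds = 3)
  expect_length(empty$cells, 0)
})
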