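test_that("lower-triangle vectorization uses the fixed edge ordering", {
  v <- matrix(0, 3, 3)
  v[2, 1] <- v[1, 2] <- 0.5
  v[3, 1] <- v[1, 3] <- -0.2
  v[3, 2] <- v[2, 3] <- 0.9
  expect_equal(vectorize_lower(network_matrix(v, "ho", 2)),
               c(0.5, -0.2, 0.9))
  ei <- lower_edge_index(3)
  expect_equal(ei$i, c(2, 3, 3))
  expect_equal(ei$j, c(1, 1, 2))

  expect_equal(length(vectorize_lower(diag(116))), 6670)
  expect_equal(nrow(lower_edge_index(116)), 116 * 115 / 2)
  expect_equal(vectorize_lower(diag(4)), rep(0, 6))
  expect_error(vectorize_lower(matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("t-test filter keeps strong effects and matches stats::t.test", {
  set.seed(101)
  n <- 20
  x <- cbind(c(rnorm(n, 0, 0.1), rnorm(n, 5, 0.1)),  # huge effect
             rnorm(2 * n),                           # null
             rnorm(2 * n))
  y <- rep(c(-1L, 1L), each = n)
  mask <- ttest_filter(x, y, 0.01)
  expect_true(mask[1])
  pv <- attr(mask, "p_values")
  for (k in 1:3) {
    ref <- t.test(x[y == 1L, k], x[y == -1L, k], var.equal = TRUE)$p.value
    expect_equal(pv[k], ref, tolerance = 1e-12)
  }
  expect_equal(which(ttest_filter(x, y, 1.0)), 1:3)
  x_const <- cbind(x, 1)
  expect_warning(m2 <- ttest_filter(x_const, y, 1.0), "zero-variance")
  expect_false(m2[4])
  expect_error(ttest_filter(x, rep(1L, 2 * n), 0.05), "both classes")
})

test_that("t-test filter has approximately nominal type-I error under the null", {
  set.seed(103)
  n_feat <- 1000
  x <- matrix(rnorm(40 * n_feat), 40, n_feat)
  y <- rep(c(-1L, 1L), each = 20)
  mask <- ttest_filter(x, y, 0.05)
  rate <- mean(mask)
  # binomial(1000, 0.05): 99.9% interval is about [0.028, 0.073]
  expect_gt(rate, 0.025)
  expect_lt(rate, 0.08)
})

test_that("LASSO selection matches a coordinate-descent oracle", {
  # independent cyclic coordinate descent on (1/2)||y - Xw||^2 + lambda|w|_1
  cd_lasso <- function(x, y, lambda, iters = 5000) {
    p <- ncol(x)
    w <- rep(0, p)
    a <- colSums(x^2)
    for (it in seq_len(iters)) {
      for (j in seq_len(p)) {
        r <- y - x %*% w + x[, j] * w[j]
        b <- sum(x[, j] * r)
        w[j] <- sign(b) * max(abs(b) - lambda, 0) / a[j]
      }
    }
    w
  }
  set.seed(107)
  n <- 30; p <- 6
  x <- scale(matrix(rnorm(n * p), n, p))
  beta <- c(2, -1.5, 0, 0, 1, 0)
  y <- sign(drop(x %*% beta) + rnorm(n, 0, 0.5))
  x <- scale(x)
  lam <- 0.2 * lasso_max_lambda(x, y)
  mask <- lasso_select(x, y, lam)
  w_ref <- cd_lasso(x, y, lam)
  expect_lt(max(abs(attr(mask, "coefficients") - w_ref)), 1e-6)
  expect_identical(as.logical(mask), abs(w_ref) > 1e-8)
})

test_that("LASSO support shrinks with the penalty and vanishes at lambda_max", {
  set.seed(109)
  n <- 40; p <- 12
  x <- scale(matrix(rnorm(n * p), n, p))
  y <- rep(c(-1, 1), each = 20)[sample(n)]
  lmax <- lasso_max_lambda(x, y)
  expect_false(any(lasso_select(x, y, lmax * 1.0001)))
  ratios <- 10^seq(log10(0.01), 0, length.out = 10)
  masks <- homnet:::lasso_path_masks(x, y, ratios * lmax)
  sizes <- colSums(masks)
  expect_true(all(diff(sizes) <= 0))
  # lambda = 0 with full-rank design: ordinary least squares, all retained
  m0 <- lasso_select(x, y, 0)
  expect_equal(sum(m0), p)
})

test_that("the linear SVM separates what a hyperplane can and not more", {
  x <- rbind(c(0, 0), c(1, 1))
  y <- c(-1L, 1L)
  fit <- train_svm(x, y, cost = 10)
  expect_equal(predict(fit, x), y)

  xor_x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  xor_y <- c(-1L, 1L, 1L, -1L)
  fit_xor <- train_svm(xor_x, xor_y, cost = 10)
  expect_lte(mean(predict(fit_xor, xor_x) == xor_y), 0.75)

  set.seed(113)
  n <- 100
  xg <- rbind(matrix(rnorm(n, -1, 0.5), n / 2, 2),
              matrix(rnorm(n, 1, 0.5), n / 2, 2))
  yg <- rep(c(-1L, 1L), each = n / 2)
  test_x <- rbind(matrix(rnorm(n, -1, 0.5), n / 2, 2),
                  matrix(rnorm(n, 1, 0.5), n / 2, 2))
  fit_g <- train_svm(xg, yg, cost = 1)
  expect_gt(mean(predict(fit_g, test_x) == yg), 0.8)

  expect_error(train_svm(xg, rep(1L, n)), "single-class")
})

test_that("classification metrics reproduce the defining ratios", {
  perfect <- classification_metrics(c(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unname(perfect), c(100, 100, 100, 100))
  m <- classification_metrics(c(TP = 8, FN = 2, TN = 7, FP = 3))
  expect_equal(m[["ACC"]], 75.0)
  expect_equal(m[["TPR"]], 80.0)
  expect_equal(m[["TNR"]], 70.0)
  expect_equal(m[["F1"]], 100 * 16 / 21, tolerance = 1e-12)
  expect_warning(u <- classification_metrics(c(TP = 0, TN = 5, FP = 2, FN = 0)),
                 "TPR undefined")
  expect_true(is.na(u[["TPR"]]))
  expect_false(is.na(u[["ACC"]]))
})

test_that("nested cross-validation is reproducible and leak-free", {
  set.seed(127)
  n <- 24
  x <- matrix(rnorm(n * 15), n, 15)
  y <- rep(c(-1L, 1L), each = n / 2)
  x[y == 1L, 1:3] <- x[y == 1L, 1:3] + 1.5
  cv1 <- nested_cv(x, y, repetitions = 2, seed = 42,
                   lambda_ratios = 10^seq(-2, 0, length.out = 4),
                   c_grid = c(0.1, 1))
  cv2 <- nested_cv(x, y, repetitions = 2, seed = 42,
                   lambda_ratios = 10^seq(-2, 0, length.out = 4),
                   c_grid = c(0.1, 1))
  expect_identical(cv1$metrics, cv2$metrics)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  # every subject predicted exactly once per repetition
  expect_false(anyNA(cv1$predictions))
  expect_equal(dim(cv1$predictions), c(2, n))
  # fold count bookkeeping
  expect_equal(nrow(cv1$fold_metrics), 2 * 5)

  # corrupting held-out labels must not change training-fold selections
  fold <- cv1$fold_assignment[1, ]
  test_idx <- which(fold == 1)
  train_idx <- which(fold != 1)
  set.seed(999)
  res_clean <- homnet:::fit_outer_fold(
    x, y, train_idx, test_idx, p_grid = c(0.05, 0.1),
    lambda_ratios = c(0.1, 0.5), c_grid = 1, n_inner = 3)
  y_bad <- y
  y_bad[test_idx] <- -y_bad[test_idx]
  set.seed(999)
  res_bad <- homnet:::fit_outer_fold(
    x, y_bad, train_idx, test_idx, p_grid = c(0.05, 0.1),
    lambda_ratios = c(0.1, 0.5), c_grid = 1, n_inner = 3)
  expect_identical(res_clean$mask, res_bad$mask)
  expect_identical(res_clean$pred, res_bad$pred)
  expect_identical(res_clean$lambda, res_bad$lambda)
})

test_that("pooled accuracy equals the mean of per-fold accuracies for equal folds", {
  set.seed(131)
  n <- 40   # 20 per class: every fold has exactly 8 subjects
  x <- matrix(rnorm(n * 10), n, 10)
  y <- rep(c(-1L, 1L), each = n / 2)
  x[y == 1L, 1] <- x[y == 1L, 1] + 2
  cv <- nested_cv(x, y, repetitions = 1, seed = 17,
                  p_grid = 0.1, lambda_ratios = c(0.1, 0.5), c_grid = 1)
  pooled_acc <- 100 * (cv$pooled[["TP"]] + cv$pooled[["TN"]]) / n
  expect_equal(pooled_acc, cv$metrics[["ACC"]], tolerance = 1e-10)
})

test_that("selection frequency counts folds in which a feature survives", {
  rec <- function(on) list(rep = 1, fold = 1, mask = on)
  records <- c(replicate(49, rec(c(TRUE, FALSE, TRUE)), simplify = FALSE),
               list(rec(c(FALSE, FALSE, TRUE))))
  freq <- selection_frequency(records)
  expect_equal(freq, c(49 / 50, 0, 1))
  expect_error(selection_frequency(list(rec(c(TRUE, TRUE)), rec(TRUE))),
               "inconsistent feature dimension")
  expect_error(selection_frequency(list()), "no selection records")
})

test_that("small-cohort and single-class contracts are enforced", {
  x <- matrix(rnorm(8 * 5), 8, 5)
  expect_error(nested_cv(x, rep(c(-1L, 1L), 4), repetitions = 1),
               "at least 10 subjects")
  x2 <- matrix(rnorm(12 * 5), 12, 5)
  expect_error(nested_cv(x2, rep(1L, 12), repetitions = 1), "both classes")
})
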