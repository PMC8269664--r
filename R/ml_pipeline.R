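#' Edge index for the strict lower triangle
#'
#' Fixed bijection between the R(R-1)/2 features of a vectorized symmetric
#' network and region pairs, in column-major order over the strict lower
#' triangle: (2,1), (3,1), ..., (R,1), (3,2), ...  Indices are 1-based.
#'
#' @param R Number of regions.
#' @return Data frame with columns `feature`, `i`, `j` (i > j).
#' @export
lower_edge_index <- function(R) {
  idx <- which(lower.tri(matrix(0, R, R)), arr.ind = TRUE)
  data.frame(feature = seq_len(nrow(idx)), i = idx[, 1], j = idx[, 2])
}

#' Vectorize the lower off-diagonal triangle of a network
#'
#' @param net A [network_matrix()] or symmetric numeric matrix.
#' @return Numeric vector of length R(R-1)/2 in the [lower_edge_index()]
#'   order.
#' @export
vectorize_lower <- function(net) {
  v <- unclass(as.matrix(net))
  if (nrow(v) != ncol(v) || max(abs(v - t(v))) > 1e-10) {
    stop("vectorize_lower expects a square symmetric matrix")
  }
  v[lower.tri(v)]
}

#' Assemble a feature table from per-subject networks
#'
#' @param networks List of [network_matrix()] objects, one per subject, all
#'   the same size and kind.
#' @param labels Integer vector of +1/-1 class labels aligned with
#'   `networks`.
#' @param network_tag Short tag naming the feature type (e.g. `"Ho(8)"`).
#' @return An object of class `feature_table`: list with `x` (L x p matrix),
#'   `y`, `edge_index`, `network_tag`.
#' @export
feature_table <- function(networks, labels, network_tag = "") {
  stopifnot(length(networks) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be +1 or -1")
  x <- do.call(rbind, lapply(networks, vectorize_lower))
  structure(list(x = x, y = labels,
                 edge_index = lower_edge_index(nrow(networks[[1]])),
                 network_tag = network_tag),
            class = "feature_table")
}

#' Two-sample t-test feature filter
#'
#' Vectorized pooled-variance (Student) two-sample t-test for every feature
#' between the +1 and -1 groups; keeps features with two-sided p below the
#' threshold.  Zero-variance features (undefined t) are dropped with a
#' warning.
#'
#' @param x L x p feature matrix.
#' @param y +1/-1 labels (both classes with >= 2 samples).
#' @param p_threshold Two-sided p-value threshold.
#' @return Logical mask of length p with the p-values as attribute
#'   `"p_values"`.
#' @export
ttest_filter <- function(x, y, p_threshold) {
  p <- ttest_pvalues(x, y)
  mask <- !is.na(p) & p < p_threshold
  if (anyNA(p)) {
    warning(sum(is.na(p)), " zero-variance features excluded from the t-test filter")
  }
  attr(mask, "p_values") <- p
  mask
}

ttest_pvalues <- function(x, y) {
  g1 <- y == 1L; g2 <- y == -1L
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L) {
    stop("two-sample t-test needs both classes with at least 2 samples")
  }
  x1 <- x[g1, , drop = FALSE]; x2 <- x[g2, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums(sweep(x1, 2L, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(x2, 2L, m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  pv <- 2 * stats::pt(-abs(tt), df = n1 + n2 - 2)
  pv[se == 0] <- NA_real_
  pv
}

#' Largest useful LASSO penalty
#'
#' For the penalized least-squares objective
#' (1/2)||y - X w||^2 + lambda ||w||_1 with no intercept, every coefficient
#' is zero once lambda >= max |X^T y|.
#'
#' @param x Column-standardized design matrix.
#' @param y +1/-1 labels.
#' @return The scalar lambda_max.
#' @export
lasso_max_lambda <- function(x, y) {
  max(abs(crossprod(x, y)))
}

# Support masks along a lambda path for (1/2)RSS + lambda*L1, no intercept.
# glmnet solves (1/(2n))RSS + lambda_g*L1, so lambda_g = lambda / n.
lasso_path_masks <- function(x, y, lambdas) {
  n <- nrow(x); p <- ncol(x)
  if (p == 1L) {
    b <- sum(x * y); a <- sum(x^2)
    beta <- vapply(lambdas, function(l) sign(b) * max(abs(b) - l, 0) / a,
                   numeric(1))
    return(matrix(abs(beta) > 1e-8, nrow = 1L))
  }
  ord <- order(lambdas, decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                        lambda = lambdas[ord] / n, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-10)
  beta <- as.matrix(fit$beta)
  masks <- matrix(FALSE, p, length(lambdas))
  masks[, ord] <- abs(beta) > 1e-8
  masks
}

#' LASSO feature selection
#'
#' Solves the L1-penalized least-squares problem
#' (1/2) sum_l (I_l - <y_l, w>)^2 + lambda ||w||_1 (no intercept) on a
#' column-standardized design and returns the support of the solution.
#'
#' @param x Column-standardized L x p design matrix.
#' @param y +1/-1 labels.
#' @param lambda Nonnegative penalty weight (on the (1/2)RSS scale).
#' @return Logical mask, `TRUE` where `|w| > 1e-8`, with the fitted
#'   coefficients as attribute `"coefficients"`.
#' @export
lasso_select <- function(x, y, lambda) {
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite input")
  if (lambda < 0) stop("lambda must be nonnegative")
  n <- nrow(x); p <- ncol(x)
  if (p == 1L) {
    b <- sum(x * y); a <- sum(x^2)
    beta <- sign(b) * max(abs(b) - lambda, 0) / a
  } else {
    lmax <- max(lasso_max_lambda(x, y), lambda, .Machine$double.eps)
    path <- exp(seq(log(lmax * 1.001), log(max(lambda, lmax * 1e-4)),
                    length.out = 25L))
    if (lambda < path[length(path)]) path <- c(path, lambda)
    fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                          lambda = path / n, standardize = FALSE,
                          intercept = FALSE, thresh = 1e-12)
    beta <- as.numeric(as.matrix(fit$beta)[, ncol(fit$beta)])
  }
  mask <- abs(beta) > 1e-8
  attr(mask, "coefficients") <- beta
  mask
}

#' Train a linear soft-margin SVM
#'
#' @param x Training design matrix (already standardized/selected).
#' @param y +1/-1 labels, both classes present.
#' @param cost Soft-margin cost C.
#' @return A fitted linear SVM of class `homnet_svm`.
#' @export
train_svm <- function(x, y, cost = 1) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("single-class training set")
  fit <- e1071::svm(x = as.matrix(x), y = factor(y, levels = c(-1L, 1L)),
                    kernel = "linear", cost = cost, scale = FALSE)
  structure(list(fit = fit), class = "homnet_svm")
}

#' @rdname train_svm
#' @param object A `homnet_svm`.
#' @param newdata Matrix with the same columns as the training design.
#' @param ... Unused.
#' @return `predict()`: integer vector of +1/-1 labels.
#' @export
predict.homnet_svm <- function(object, newdata, ...) {
  as.integer(as.character(stats::predict(object$fit, as.matrix(newdata))))
}

#' Classification metrics from confusion counts
#'
#' ACC = (TP+TN)/(TP+FP+TN+FN), TPR = TP/(TP+FN), TNR = TN/(FP+TN),
#' F1 = 2TP/(2TP+FN+FP), each reported as a percentage.  A metric with a zero
#' denominator is returned as `NA` with a warning, not as 0.
#'
#' @param counts Named numeric vector or list with elements TP, TN, FP, FN.
#' @return Named numeric vector `c(ACC, TPR, TNR, F1)` in percent.
#' @export
classification_metrics <- function(counts) {
  counts <- unlist(counts)[c("TP", "TN", "FP", "FN")]
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be nonnegative numbers named TP, TN, FP, FN")
  }
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NA_real_)
    }
    100 * num / den
  }
  c(ACC = ratio(tp + tn, tp + fp + tn + fn, "ACC"),
    TPR = ratio(tp, tp + fn, "TPR"),
    TNR = ratio(tn, fp + tn, "TNR"),
    F1 = ratio(2 * tp, 2 * tp + fn + fp, "F1"))
}

confusion_counts <- function(truth, pred) {
  c(TP = sum(truth == 1L & pred == 1L),
    TN = sum(truth == -1L & pred == -1L),
    FP = sum(truth == -1L & pred == 1L),
    FN = sum(truth == 1L & pred == -1L))
}

# Stratified k-fold assignment: within each class, indices are shuffled and
# dealt round-robin starting from a random fold, so fold sizes differ by at
# most one and class balance is preserved as far as counts allow.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    start <- sample.int(k, 1L)
    fold[idx] <- ((start - 1L + seq_along(idx) - 1L) %% k) + 1L
  }
  for (f in seq_len(k)) {
    if (length(unique(y[fold != f])) < 2L) {
      stop("impossible stratification: a training fold has a single class")
    }
  }
  fold
}

std_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

std_apply <- function(x, st) {
  sweep(sweep(x, 2L, st$mu), 2L, st$sd, "/")
}

# Inner-loop grid search over (p_threshold, lambda ratio, C) by mean inner
# k-fold accuracy.  lambda is parameterized as ratio * lambda_max, with
# lambda_max recomputed on each (standardized, t-filtered) training design so
# the tuned quantity transfers across folds.  Ties: larger lambda ratio, then
# smaller C, then smaller p_threshold.
tune_hyperparams <- function(x, y, p_grid, lambda_ratios, c_grid, n_inner) {
  fold <- stratified_folds(y, n_inner)
  acc <- array(0, dim = c(length(p_grid), length(lambda_ratios),
                          length(c_grid)))
  for (f in seq_len(n_inner)) {
    tr <- fold != f; va <- fold == f
    xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
    xva <- x[va, , drop = FALSE]; yva <- y[va]
    st <- std_fit(xtr)
    xtr_s <- std_apply(xtr, st); xva_s <- std_apply(xva, st)
    maj <- if (sum(ytr == 1L) >= sum(ytr == -1L)) 1L else -1L
    maj_acc <- mean(yva == maj)
    pvals <- ttest_pvalues(xtr, ytr)
    for (pi in seq_along(p_grid)) {
      tmask <- !is.na(pvals) & pvals < p_grid[pi]
      if (!any(tmask)) {
        acc[pi, , ] <- acc[pi, , ] + maj_acc
        next
      }
      xs <- xtr_s[, tmask, drop = FALSE]
      lmax <- lasso_max_lambda(xs, ytr)
      masks <- lasso_path_masks(xs, ytr, lambda_ratios * lmax)
      for (li in seq_along(lambda_ratios)) {
        sel <- masks[, li]
        if (!any(sel)) {
          acc[pi, li, ] <- acc[pi, li, ] + maj_acc
          next
        }
        for (ci in seq_along(c_grid)) {
          model <- train_svm(xs[, sel, drop = FALSE], ytr, cost = c_grid[ci])
          pred <- predict(model, xva_s[, tmask, drop = FALSE][, sel,
                                                             drop = FALSE])
          acc[pi, li, ci] <- acc[pi, li, ci] + mean(pred == yva)
        }
      }
    }
  }
  acc <- acc / n_inner
  combos <- expand.grid(pi = seq_along(p_grid), li = seq_along(lambda_ratios),
                        ci = seq_along(c_grid))
  combos$acc <- acc[as.matrix(combos)]
  ord <- order(-combos$acc, -combos$li, combos$ci, combos$pi)
  best <- combos[ord[1L], ]
  list(p_threshold = p_grid[best$pi],
       lambda_ratio = lambda_ratios[best$li],
       C = c_grid[best$ci],
       inner_accuracy = best$acc)
}

# Fit one outer fold: tune on the training subjects only, refit the full
# selection + SVM on them, and predict the held-out fold.  Test labels are
# never touched before evaluation.
fit_outer_fold <- function(x, y, train_idx, test_idx, p_grid, lambda_ratios,
                           c_grid, n_inner) {
  xtr <- x[train_idx, , drop = FALSE]; ytr <- y[train_idx]
  tuned <- tune_hyperparams(xtr, ytr, p_grid, lambda_ratios, c_grid, n_inner)
  st <- std_fit(xtr)
  xtr_s <- std_apply(xtr, st)
  pvals <- ttest_pvalues(xtr, ytr)
  tmask <- !is.na(pvals) & pvals < tuned$p_threshold
  p <- ncol(x)
  full_mask <- logical(p)
  fallback <- FALSE
  lambda <- NA_real_
  if (any(tmask)) {
    xs <- xtr_s[, tmask, drop = FALSE]
    lambda <- tuned$lambda_ratio * lasso_max_lambda(xs, ytr)
    lmask <- lasso_select(xs, ytr, lambda)
    full_mask[which(tmask)[lmask]] <- TRUE
  }
  if (any(full_mask)) {
    model <- train_svm(xtr_s[, full_mask, drop = FALSE], ytr, cost = tuned$C)
    xte_s <- std_apply(x[test_idx, , drop = FALSE], st)
    pred <- predict(model, xte_s[, full_mask, drop = FALSE])
  } else {
    fallback <- TRUE
    maj <- if (sum(ytr == 1L) >= sum(ytr == -1L)) 1L else -1L
    pred <- rep(maj, length(test_idx))
  }
  list(pred = pred, mask = full_mask, p_threshold = tuned$p_threshold,
       lambda_ratio = tuned$lambda_ratio, lambda = lambda, C = tuned$C,
       inner_accuracy = tuned$inner_accuracy, fallback = fallback)
}

#' Repeated stratified nested cross-validation
#'
#' Evaluates the full t-test + LASSO + linear SVM pipeline by repeated
#' stratified 5-fold cross-validation: in each repetition the cohort is
#' split into `n_outer` stratified folds; for each outer fold the
#' hyperparameters (t-test p threshold, LASSO penalty, SVM cost) are chosen
#' by an inner `n_inner`-fold grid search on the training subjects only, the
#' pipeline is refit on those subjects, and the held-out fold is predicted
#' exactly once.  Feature standardization statistics, t-test p-values and the
#' LASSO path are all computed on training subjects only.
#'
#' @param table A [feature_table()], or a plain L x p matrix (then `y` must
#'   be supplied).
#' @param y +1/-1 labels when `table` is a matrix.
#' @param repetitions Number of independent fold partitions (10 to match the
#'   standard 10-times five-fold protocol; smaller for quick runs).
#' @param seed Master seed; every random choice derives from it, so the same
#'   seed reproduces the result exactly.
#' @param p_grid Candidate t-test p-value thresholds.
#' @param lambda_ratios Candidate LASSO penalties as fractions of
#'   lambda_max; default 10-point log grid from 0.01 to 1.
#' @param c_grid Candidate SVM costs.
#' @param n_outer,n_inner Outer/inner fold counts (default 5/5).
#' @return An object of class `homnet_cv`: aggregate `metrics` (percent,
#'   mean over all outer folds), `fold_metrics` data frame, `records` of
#'   per-fold selection masks and tuned hyperparameters, out-of-fold
#'   `predictions` (repetitions x L), `fold_assignment`, pooled confusion
#'   counts, and the inputs needed to align ensembles (`y`, `seed`,
#'   `repetitions`, `network_tag`).
#' @export
nested_cv <- function(table, y = NULL, repetitions = 10, seed = 1,
                      p_grid = c(0.01, 0.05, 0.1),
                      lambda_ratios = 10^seq(log10(0.01), 0, length.out = 10),
                      c_grid = c(0.1, 1, 10),
                      n_outer = 5, n_inner = 5) {
  if (inherits(table, "feature_table")) {
    x <- table$x; y <- table$y; tag <- table$network_tag
  } else {
    x <- as.matrix(table); tag <- ""
    if (is.null(y)) stop("y must be supplied when table is a matrix")
    y <- as.integer(y)
  }
  L <- nrow(x)
  if (L < 10L) stop("need at least 10 subjects for nested cross-validation")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, repetitions)
  predictions <- matrix(NA_integer_, repetitions, L)
  fold_assignment <- matrix(NA_integer_, repetitions, L)
  records <- list()
  fm <- list()
  for (r in seq_len(repetitions)) {
    set.seed(rep_seeds[r])
    fold <- stratified_folds(y, n_outer)
    fold_assignment[r, ] <- fold
    for (f in seq_len(n_outer)) {
      test_idx <- which(fold == f)
      train_idx <- which(fold != f)
      res <- fit_outer_fold(x, y, train_idx, test_idx, p_grid, lambda_ratios,
                            c_grid, n_inner)
      predictions[r, test_idx] <- res$pred
      cc <- confusion_counts(y[test_idx], res$pred)
      met <- suppressWarnings(classification_metrics(cc))
      fm[[length(fm) + 1L]] <- data.frame(
        rep = r, fold = f, TP = cc[["TP"]], TN = cc[["TN"]], FP = cc[["FP"]],
        FN = cc[["FN"]], ACC = met[["ACC"]], TPR = met[["TPR"]],
        TNR = met[["TNR"]], F1 = met[["F1"]])
      records[[length(records) + 1L]] <- list(
        rep = r, fold = f, mask = res$mask, p_threshold = res$p_threshold,
        lambda_ratio = res$lambda_ratio, lambda = res$lambda, C = res$C,
        inner_accuracy = res$inner_accuracy, fallback = res$fallback)
    }
  }
  fold_metrics <- do.call(rbind, fm)
  pooled <- c(TP = sum(fold_metrics$TP), TN = sum(fold_metrics$TN),
              FP = sum(fold_metrics$FP), FN = sum(fold_metrics$FN))
  metrics <- colMeans(fold_metrics[, c("ACC", "TPR", "TNR", "F1")],
                      na.rm = TRUE)
  structure(list(metrics = metrics, fold_metrics = fold_metrics,
                 records = records, predictions = predictions,
                 fold_assignment = fold_assignment, pooled = pooled,
                 y = y, seed = seed, repetitions = repetitions,
                 n_outer = n_outer, network_tag = tag),
            class = "homnet_cv")
}

#' @export
print.homnet_cv <- function(x, ...) {
  cat(sprintf(
    "<homnet_cv>%s %d x %d-fold CV over %d subjects (seed %d)\n",
    if (nzchar(x$network_tag)) paste0(" [", x$network_tag, "]") else "",
    x$repetitions, x$n_outer, length(x$y), x$seed))
  print(round(x$metrics, 2))
  invisible(x)
}

#' Per-feature selection frequency across cross-validation folds
#'
#' The fraction of outer folds (over all repetitions) in which each feature
#' survives the t-test + LASSO selection; with 10 repetitions of 5 folds a
#' feature selected 49 times has frequency 49/50 = 0.98.
#'
#' @param records A `homnet_cv` object, or its list of per-fold selection
#'   records.
#' @return Numeric vector of frequencies in [0, 1], one per feature.
#' @export
selection_frequency <- function(records) {
  if (inherits(records, "homnet_cv")) records <- records$records
  if (length(records) == 0L) stop("no selection records")
  p <- length(records[[1L]]$mask)
  if (!all(vapply(records, function(r) length(r$mask), integer(1)) == p)) {
    stop("inconsistent feature dimension across selection records")
  }
  m <- vapply(records, function(r) as.logical(r$mask), logical(p))
  rowMeans(matrix(m, nrow = p))
}
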