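#' Panel of per-learner predictions for voting
#'
#' @param predictions T x L integer matrix of +1/-1 predictions: one row per
#'   learner (network-specific classifier), one column per subject.
#' @param learner_tags Character vector of length T naming the learners
#'   (e.g. `"C"`, `"CM(2)"`, `"Ho(8)"`).
#' @return An object of class `vote_panel`.
#' @export
vote_panel <- function(predictions, learner_tags = NULL) {
  predictions <- as.matrix(predictions)
  if (nrow(predictions) < 1L) stop("empty panel: need at least one learner")
  if (!all(predictions %in% c(-1L, 1L))) {
    stop("all predictions must be +1 or -1")
  }
  if (is.null(learner_tags)) {
    learner_tags <- paste0("learner_", seq_len(nrow(predictions)))
  }
  stopifnot(length(learner_tags) == nrow(predictions))
  structure(list(predictions = predictions, learner_tags = learner_tags),
            class = "vote_panel")
}

#' Majority vote over a panel of learners
#'
#' A subject is assigned the label that receives more than half of the T
#' votes.  With an even panel a tie is possible; the tied subject is rejected
#' and, when a `fallback` learner is designated, resolved to that learner's
#' vote.  With odd T and binary labels no rejection can occur.
#'
#' @param panel A [vote_panel()].
#' @param fallback Index (or tag) of the learner whose vote resolves ties;
#'   `NULL` leaves rejected subjects as `NA`.
#' @return List with `labels` (integer +1/-1, `NA` where rejected and
#'   unresolved) and `rejected` (logical).
#' @export
majority_vote <- function(panel, fallback = NULL) {
  stopifnot(inherits(panel, "vote_panel"))
  pr <- panel$predictions
  t_n <- nrow(pr)
  pos <- colSums(pr == 1L)
  labels <- rep(NA_integer_, ncol(pr))
  labels[pos > t_n / 2] <- 1L
  labels[(t_n - pos) > t_n / 2] <- -1L
  rejected <- is.na(labels)
  if (any(rejected) && !is.null(fallback)) {
    if (is.character(fallback)) {
      fallback <- match(fallback, panel$learner_tags)
      if (is.na(fallback)) stop("unknown fallback learner tag")
    }
    labels[rejected] <- pr[fallback, rejected]
  }
  list(labels = labels, rejected = rejected)
}

#' Evaluate a voting strategy over aligned cross-validation results
#'
#' Combines the out-of-fold predictions of several network-specific
#' classifiers by majority vote, repetition by repetition, and scores the
#' combined predictions with the usual confusion-matrix metrics.  All members
#' must have been evaluated under identical fold partitions (same cohort,
#' same seed and repetitions), otherwise their out-of-fold predictions do
#' not align and the combination is refused.  Ties (possible only with an
#' even number of members) are resolved by the member with the highest
#' aggregate accuracy.
#'
#' @param cv_results Named list of `homnet_cv` objects, one per member
#'   network; names are used as learner tags.
#' @return List with aggregate `metrics` (percent, mean over all outer folds
#'   of all repetitions — the same aggregation as [nested_cv()], so a
#'   one-member strategy reproduces that member's metrics exactly),
#'   `fold_metrics` data frame, combined `predictions` (repetitions x L) and
#'   the member `tags`.
#' @export
evaluate_strategy <- function(cv_results) {
  if (length(cv_results) < 1L) stop("empty strategy")
  stopifnot(all(vapply(cv_results, inherits, logical(1), "homnet_cv")))
  ref <- cv_results[[1L]]
  for (m in cv_results[-1L]) {
    if (!identical(m$y, ref$y) ||
        !identical(m$fold_assignment, ref$fold_assignment)) {
      stop("mismatched fold partitions across members: ",
           "voting requires aligned out-of-fold predictions ",
           "(same cohort, seed and repetitions)")
    }
  }
  tags <- names(cv_results)
  if (is.null(tags)) tags <- paste0("member_", seq_along(cv_results))
  fallback <- which.max(vapply(cv_results, function(m) m$metrics[["ACC"]],
                               numeric(1)))
  reps <- ref$repetitions
  L <- length(ref$y)
  combined <- matrix(NA_integer_, reps, L)
  fm_list <- list()
  for (r in seq_len(reps)) {
    panel <- vote_panel(do.call(rbind, lapply(cv_results,
                                              function(m) m$predictions[r, ])),
                        learner_tags = tags)
    combined[r, ] <- majority_vote(panel, fallback = fallback)$labels
    # score fold by fold, mirroring the per-member CV aggregation exactly
    for (f in sort(unique(ref$fold_assignment[r, ]))) {
      idx <- ref$fold_assignment[r, ] == f
      cc <- confusion_counts(ref$y[idx], combined[r, idx])
      met <- suppressWarnings(classification_metrics(cc))
      fm_list[[length(fm_list) + 1L]] <- data.frame(
        rep = r, fold = f, TP = cc[["TP"]], TN = cc[["TN"]], FP = cc[["FP"]],
        FN = cc[["FN"]], ACC = met[["ACC"]], TPR = met[["TPR"]],
        TNR = met[["TNR"]], F1 = met[["F1"]])
    }
  }
  fold_metrics <- do.call(rbind, fm_list)
  metrics <- colMeans(fold_metrics[, c("ACC", "TPR", "TNR", "F1")],
                      na.rm = TRUE)
  list(metrics = metrics, fold_metrics = fold_metrics,
       predictions = combined, tags = tags)
}

#' Named voting strategies over standard network tags
#'
#' Reference list of the classic 3/5/7-member combinations of the static
#' network (`C`), the RMS baseline, moment networks `CM(d)` and high-order
#' networks `Ho(d)`, keyed A through J.
#'
#' @return Named list of character vectors of member tags.
#' @export
standard_strategies <- function() {
  list(
    A = c("C", "CM(2)", "Ho(8)"),
    B = c("RMS", "CM(2)", "Ho(8)"),
    C = c("CM(2)", "CM(4)", "CM(10)"),
    D = c("Ho(6)", "Ho(8)", "Ho(10)"),
    E = c("C", "CM(2)", "CM(4)", "CM(10)", "Ho(8)"),
    F = c("RMS", "CM(2)", "CM(4)", "CM(10)", "Ho(8)"),
    G = c("C", "CM(2)", "Ho(6)", "Ho(8)", "Ho(10)"),
    H = c("RMS", "CM(2)", "Ho(6)", "Ho(8)", "Ho(10)"),
    I = c("C", "CM(2)", "CM(4)", "CM(10)", "Ho(6)", "Ho(8)", "Ho(10)"),
    J = c("RMS", "CM(2)", "CM(4)", "CM(10)", "Ho(6)", "Ho(8)", "Ho(10)")
  )
}
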