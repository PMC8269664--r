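#' Run configuration for an end-to-end experiment
#'
#' @param manifest Path to a cohort manifest CSV (ignored when `cohort` is
#'   supplied directly to [run_experiment()]).
#' @param out_dir Output directory; `NULL` keeps everything in memory.
#' @param W,s Vectors of window lengths and steps to sweep (defaults: the
#'   standard grids W = 30..100 by 10, s = 2..16 by 2).
#' @param orders Moment orders d to build.
#' @param repetitions,seed Cross-validation repetitions and master seed.
#' @param p_grid,lambda_ratios,c_grid Hyperparameter grids, see
#'   [nested_cv()].
#' @param strategies Named list of voting strategies (character vectors of
#'   network tags); `NULL` skips voting.
#' @param include_diagonal Whether the CM(d) diagonal participates in the
#'   high-order row correlations.
#' @return A `run_config` list.
#' @export
run_config <- function(manifest = NULL, out_dir = NULL,
                       W = seq(30, 100, by = 10), s = seq(2, 16, by = 2),
                       orders = 1:10, repetitions = 10, seed = 1,
                       p_grid = c(0.01, 0.05, 0.1),
                       lambda_ratios = 10^seq(log10(0.01), 0,
                                              length.out = 10),
                       c_grid = c(0.1, 1, 10), strategies = NULL,
                       include_diagonal = TRUE) {
  structure(list(manifest = manifest, out_dir = out_dir, W = W, s = s,
                 orders = as.integer(orders),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed), p_grid = p_grid,
                 lambda_ratios = lambda_ratios, c_grid = c_grid,
                 strategies = strategies,
                 include_diagonal = include_diagonal),
            class = "run_config")
}

load_cohort <- function(manifest_path) {
  manifest <- read_manifest(manifest_path)
  ts <- lapply(seq_len(nrow(manifest)), function(i) {
    read_timeseries(manifest$path[i], subject_id = manifest$subject_id[i])
  })
  list(timeseries = ts, labels = manifest$label, manifest = manifest)
}

#' Build every network tag's feature table for one (W, s) setting
#'
#' @param cohort List with `timeseries` and `labels` (as produced by
#'   [simulate_cohort()] or [run_experiment()]'s manifest loader).
#' @param spec A [sliding_window_spec()].
#' @param orders Moment orders to build.
#' @param include_diagonal Passed to [build_hofcn()].
#' @return Named list of [feature_table()] objects keyed by network tag
#'   (`"C"`, `"RMS"`, `"CM(d)"`, `"Ho(d)"`).
#' @export
cohort_feature_tables <- function(cohort, spec, orders = 1:10,
                                  include_diagonal = TRUE) {
  nets <- lapply(cohort$timeseries, build_all_networks, spec = spec,
                 orders = orders, include_diagonal = include_diagonal)
  tabs <- list()
  tabs[["C"]] <- feature_table(lapply(nets, `[[`, "cfcn"), cohort$labels, "C")
  tabs[["RMS"]] <- feature_table(lapply(nets, `[[`, "rms"), cohort$labels,
                                 "RMS")
  for (d in orders) {
    dd <- as.character(d)
    tabs[[sprintf("CM(%d)", d)]] <- feature_table(
      lapply(nets, function(n) n$cm[[dd]]), cohort$labels,
      sprintf("CM(%d)", d))
    tabs[[sprintf("Ho(%d)", d)]] <- feature_table(
      lapply(nets, function(n) n$ho[[dd]]), cohort$labels,
      sprintf("Ho(%d)", d))
  }
  tabs
}

#' Run the full experiment: networks, classification, voting
#'
#' Executes the whole pipeline for every (W, s) combination in the config:
#' builds the dynamic, static, RMS, CM(d) and Ho(d) networks for every
#' subject, evaluates each network tag with repeated stratified nested
#' cross-validation (all tags share the master seed, so their fold
#' partitions align), and optionally combines tags by majority voting.
#' When `out_dir` is set, writes `metrics.csv` (one row per W, s, tag),
#' `vote_metrics.csv`, per-tag selection-frequency CSVs, and a provenance
#' log recording the seed and grids.  Re-running the same config reproduces
#' every output exactly.
#'
#' @param config A [run_config()].
#' @param cohort Optional in-memory cohort (list with `timeseries`,
#'   `labels`); when `NULL` the manifest in `config` is loaded.
#' @return List with `metrics` (data frame), `votes` (data frame or NULL),
#'   and `cv` (nested list of `homnet_cv` keyed by "W_s" then tag).
#' @export
run_experiment <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    if (is.null(config$manifest)) stop("config has no manifest and no cohort given")
    cohort <- load_cohort(config$manifest)
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  metrics_rows <- list()
  vote_rows <- list()
  cv_all <- list()
  for (w in config$W) {
    for (st in config$s) {
      spec <- sliding_window_spec(w, st)
      key <- sprintf("W%d_s%d", w, st)
      tabs <- cohort_feature_tables(cohort, spec, config$orders,
                                    config$include_diagonal)
      cvs <- list()
      for (tag in names(tabs)) {
        cv <- nested_cv(tabs[[tag]], repetitions = config$repetitions,
                        seed = config$seed, p_grid = config$p_grid,
                        lambda_ratios = config$lambda_ratios,
                        c_grid = config$c_grid)
        cvs[[tag]] <- cv
        metrics_rows[[length(metrics_rows) + 1L]] <- data.frame(
          W = w, s = st, tag = tag, ACC = cv$metrics[["ACC"]],
          TPR = cv$metrics[["TPR"]], TNR = cv$metrics[["TNR"]],
          F1 = cv$metrics[["F1"]])
        if (!is.null(out_dir)) {
          freq <- selection_frequency(cv)
          ei <- tabs[[tag]]$edge_index
          utils::write.csv(
            data.frame(i = ei$i, j = ei$j, frequency = freq),
            file.path(out_dir, sprintf("selection_%s_%s.csv", key,
                                       gsub("[()]", "", tag))),
            row.names = FALSE)
        }
      }
      cv_all[[key]] <- cvs
      if (!is.null(config$strategies)) {
        for (sn in names(config$strategies)) {
          members <- config$strategies[[sn]]
          missing <- setdiff(members, names(cvs))
          if (length(missing) > 0L) {
            warning("strategy ", sn, " skipped: unknown tags ",
                    paste(missing, collapse = ", "))
            next
          }
          ev <- evaluate_strategy(cvs[members])
          vote_rows[[length(vote_rows) + 1L]] <- data.frame(
            W = w, s = st, strategy = sn,
            members = paste(members, collapse = "+"),
            ACC = ev$metrics[["ACC"]], TPR = ev$metrics[["TPR"]],
            TNR = ev$metrics[["TNR"]], F1 = ev$metrics[["F1"]])
        }
      }
    }
  }
  metrics <- do.call(rbind, metrics_rows)
  votes <- if (length(vote_rows) > 0L) do.call(rbind, vote_rows) else NULL
  if (!is.null(out_dir)) {
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    if (!is.null(votes)) {
      utils::write.csv(votes, file.path(out_dir, "vote_metrics.csv"),
                       row.names = FALSE)
    }
    writeLines(c(
      sprintf("homnet version: %s",
              as.character(utils::packageVersion("homnet"))),
      sprintf("seed: %d", config$seed),
      sprintf("repetitions: %d", config$repetitions),
      sprintf("W: %s", paste(config$W, collapse = ",")),
      sprintf("s: %s", paste(config$s, collapse = ",")),
      sprintf("orders: %s", paste(config$orders, collapse = ",")),
      sprintf("p_grid: %s", paste(config$p_grid, collapse = ",")),
      sprintf("lambda_ratios: %s",
              paste(signif(config$lambda_ratios, 6), collapse = ",")),
      sprintf("c_grid: %s", paste(config$c_grid, collapse = ","))),
      file.path(out_dir, "provenance.txt"))
  }
  list(metrics = metrics, votes = votes, cv = cv_all)
}
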