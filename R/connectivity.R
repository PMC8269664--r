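#' Sliding-window specification
#'
#' @param W Window length in time points.
#' @param s Step (stride) between consecutive windows, in time points.
#' @return An object of class `sliding_window_spec`.
#' @export
sliding_window_spec <- function(W, s) {
  W <- as.integer(W); s <- as.integer(s)
  if (is.na(W) || W < 1L) stop("window length W must be >= 1")
  if (is.na(s) || s < 1L) stop("step s must be >= 1")
  structure(list(W = W, s = s), class = "sliding_window_spec")
}

#' @export
print.sliding_window_spec <- function(x, ...) {
  cat(sprintf("<sliding_window_spec> W=%d, s=%d\n", x$W, x$s))
  invisible(x)
}

#' Sliding-window segment boundaries
#'
#' Partitions a series of M time points into K = floor((M - W)/s) + 1
#' overlapping segments of length W with stride s.  A trailing partial window
#' (when M - W is not divisible by s) is dropped, so every segment has the
#' full length W.  Segments are half-open 0-based internally; the returned
#' table reports 1-based inclusive bounds.
#'
#' @param M Number of time points.
#' @param spec A [sliding_window_spec()] (or window length `W` when `s` is
#'   given).
#' @param s Step, used only when `spec` is a plain number.
#' @return A data frame with columns `window` (1-based index), `start`, `end`
#'   (1-based inclusive time-point bounds).
#' @export
window_segments <- function(M, spec, s = NULL) {
  if (!inherits(spec, "sliding_window_spec")) {
    spec <- sliding_window_spec(spec, s)
  }
  M <- as.integer(M)
  if (spec$W > M) {
    stop(sprintf("window length W=%d exceeds series length M=%d", spec$W, M))
  }
  K <- (M - spec$W) %/% spec$s + 1L
  start0 <- (seq_len(K) - 1L) * spec$s
  data.frame(window = seq_len(K), start = start0 + 1L, end = start0 + spec$W)
}

#' Number of sliding windows
#'
#' @inheritParams window_segments
#' @return Integer K = floor((M - W)/s) + 1.
#' @export
n_windows <- function(M, spec, s = NULL) {
  nrow(window_segments(M, spec, s))
}

# Pearson correlation matrix with the zero-variance convention: a column that
# is constant over the segment has undefined correlations, which are set to 0
# (diagonal stays 1) and counted so the caller can warn once.
safe_cor <- function(x) {
  sds <- apply(x, 2L, stats::sd)
  const <- !is.finite(sds) | sds == 0
  r <- ncol(x)
  if (any(const)) {
    cc <- matrix(0, r, r)
    ok <- which(!const)
    if (length(ok) > 1L) cc[ok, ok] <- stats::cor(x[, ok, drop = FALSE])
    if (length(ok) == 1L) cc[ok, ok] <- 1
    diag(cc) <- 1
    attr(cc, "n_undefined") <- sum(const)
    return(cc)
  }
  cc <- stats::cor(x)
  attr(cc, "n_undefined") <- 0L
  cc
}

#' Build the low-order dynamic FC network (sliding-window correlations)
#'
#' For each sliding-window segment, computes the Pearson correlation between
#' every pair of regions restricted to that segment, yielding an ordered stack
#' of K symmetric R x R matrices with unit diagonal.  A region that is
#' constant within a segment has undefined correlations there; those entries
#' are set to 0 and a single warning reports how many were affected.
#'
#' @param ts A [roi_timeseries()].
#' @param spec A [sliding_window_spec()].
#' @return An object of class `dynamic_connectivity`: list with `windows`
#'   (R x R x K array), `spec`, and `subject_id`.
#' @export
build_lodfcn <- function(ts, spec) {
  stopifnot(inherits(ts, "roi_timeseries"),
            inherits(spec, "sliding_window_spec"))
  x <- ts$values
  seg <- window_segments(nrow(x), spec)
  K <- nrow(seg)
  r <- ncol(x)
  windows <- array(NA_real_, dim = c(r, r, K))
  n_undef <- 0L
  for (k in seq_len(K)) {
    cc <- safe_cor(x[seg$start[k]:seg$end[k], , drop = FALSE])
    n_undef <- n_undef + attr(cc, "n_undefined")
    attr(cc, "n_undefined") <- NULL
    windows[, , k] <- cc
  }
  if (n_undef > 0L) {
    warning(sprintf(
      "subject '%s': %d region-window combinations had zero variance; their correlations were set to 0",
      ts$subject_id, n_undef))
  }
  structure(list(windows = windows, spec = spec, subject_id = ts$subject_id),
            class = "dynamic_connectivity")
}

#' @export
print.dynamic_connectivity <- function(x, ...) {
  cat(sprintf(
    "<dynamic_connectivity> subject '%s': %d windows of %d x %d (W=%d, s=%d)\n",
    x$subject_id, dim(x$windows)[3], dim(x$windows)[1], dim(x$windows)[2],
    x$spec$W, x$spec$s))
  invisible(x)
}

#' Build the conventional (static) FC network
#'
#' Full-length Pearson correlation matrix, i.e. the single window obtained
#' with W = M.
#'
#' @param ts A [roi_timeseries()].
#' @return A [network_matrix()] of kind `"static"`.
#' @export
build_cfcn <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  cc <- safe_cor(ts$values)
  if (attr(cc, "n_undefined") > 0L) {
    warning(sprintf(
      "subject '%s': %d constant regions; their correlations were set to 0",
      ts$subject_id, attr(cc, "n_undefined")))
  }
  attr(cc, "n_undefined") <- NULL
  network_matrix(cc, kind = "static")
}

#' Extract one edge's FC time series from a dynamic network
#'
#' @param dcn A `dynamic_connectivity` object.
#' @param i,j 1-based region indices.
#' @return Numeric vector of length K: the (i, j) correlation in each window.
#' @export
edge_series <- function(dcn, i, j) {
  stopifnot(inherits(dcn, "dynamic_connectivity"))
  r <- dim(dcn$windows)[1]
  if (i < 1L || i > r || j < 1L || j > r) {
    stop(sprintf("region index out of range [1, %d]: (%s, %s)", r, i, j))
  }
  dcn$windows[i, j, ]
}

#' Partition of regions into functional systems
#'
#' @param assignment Character (or factor) vector of length R giving each
#'   region's system label (e.g. DMN, EAN, SMN, VN, SBN, CER).
#' @return An object of class `region_partition`.
#' @export
region_partition <- function(assignment) {
  assignment <- as.character(assignment)
  if (anyNA(assignment) || any(!nzchar(assignment))) {
    stop("every region must be assigned exactly one system label")
  }
  structure(list(assignment = assignment,
                 systems = unique(assignment)),
            class = "region_partition")
}

#' Block-level interaction between functional systems
#'
#' Averages a network's entries over all region pairs between two systems
#' (and within a system, excluding self-pairs), producing the system-by-system
#' interaction matrix used to compare intra- and inter-network connectivity
#' strength between groups.
#'
#' @param net A [network_matrix()] (any kind).
#' @param part A [region_partition()] covering all R regions.
#' @return A [network_matrix()] of kind `"block"` with one row/column per
#'   system, dimnames set to the system labels.
#' @export
block_interaction <- function(net, part) {
  stopifnot(inherits(net, "network_matrix"), inherits(part, "region_partition"))
  r <- nrow(net)
  if (length(part$assignment) != r) {
    stop(sprintf("partition covers %d regions but network has %d",
                 length(part$assignment), r))
  }
  sys <- part$systems
  idx <- lapply(sys, function(s) which(part$assignment == s))
  if (any(lengths(idx) == 0L)) stop("empty block in partition")
  ns <- length(sys)
  out <- matrix(NA_real_, ns, ns, dimnames = list(sys, sys))
  v <- unclass(net)
  for (a in seq_len(ns)) {
    for (b in a:ns) {
      sub <- v[idx[[a]], idx[[b]], drop = FALSE]
      if (a == b) {
        keep <- sub[row(sub) != col(sub)]
        if (length(keep) == 0L) stop("empty block: system '", sys[a],
                                     "' has a single region")
        out[a, b] <- mean(keep)
      } else {
        out[a, b] <- out[b, a] <- mean(sub)
      }
    }
  }
  network_matrix(out, kind = "block")
}
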