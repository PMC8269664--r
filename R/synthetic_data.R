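#' Specification of a synthetic two-group cohort
#'
#' Defines a cohort of Gaussian ROI time series whose pairwise coupling
#' follows a slowly varying, piecewise-constant process: within each block of
#' `block_length` time points the target correlation matrix is fixed, and on
#' the designated `affected_edges` the block-to-block modulation has a
#' group-dependent scale (`volatility`) and asymmetry (`skew_shift`).  The
#' two groups therefore differ not in mean coupling but in the *moments* of
#' their dynamic connectivity — exactly the signal the moment-network
#' pipeline is built to detect.  Setting both groups' volatility equal gives
#' a null cohort.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param n_regions Number of regions R.
#' @param n_timepoints Number of time points M.
#' @param base_coupling Mean latent correlation between distinct regions;
#'   scalar or full R x R matrix (diagonal ignored).
#' @param block_length Length of the constant-coupling blocks, in time
#'   points; meant to match the analysis window length.
#' @param volatility Named vector `c(pos = ..., neg = ...)`: standard
#'   deviation of the block-wise coupling modulation on affected edges, per
#'   group (+1 / -1).
#' @param skew_shift Named vector `c(pos = ..., neg = ...)`: asymmetry of
#'   the modulation (0 = symmetric).
#' @param affected_edges Two-column matrix (or data frame) of 1-based region
#'   pairs carrying the group effect; defaults to a disjoint matching
#'   (2,1), (4,3), ... over the first regions, so each affected region's
#'   moment profile changes shape rather than scale and the effect remains
#'   visible to the correlation-based high-order stage.
#' @param noise_sd Observation noise standard deviation (signals have unit
#'   variance before noise).
#' @param seed Master seed; subjects get independent derived streams.
#' @return An object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_per_group = 30, n_regions = 20,
                                  n_timepoints = 120, base_coupling = 0.2,
                                  block_length = 30,
                                  volatility = c(pos = 0.3, neg = 0.05),
                                  skew_shift = c(pos = 0, neg = 0),
                                  affected_edges = NULL, noise_sd = 0.25,
                                  seed = 1) {
  if (n_per_group < 2L) stop("need at least 2 subjects per group")
  if (any(volatility < 0)) stop("volatility must be nonnegative")
  r <- as.integer(n_regions)
  if (is.null(affected_edges)) {
    n_edges <- min(10L, r %/% 2L)
    affected_edges <- cbind(seq_len(n_edges) * 2L, seq_len(n_edges) * 2L - 1L)
  }
  affected_edges <- as.matrix(affected_edges)
  if (any(affected_edges < 1L) || any(affected_edges > r) ||
      any(affected_edges[, 1] == affected_edges[, 2])) {
    stop("affected_edges must be distinct region pairs within 1..R")
  }
  if (is.matrix(base_coupling)) {
    if (!all(dim(base_coupling) == r)) stop("base_coupling matrix must be R x R")
    base <- (base_coupling + t(base_coupling)) / 2
  } else {
    base <- matrix(base_coupling, r, r)
  }
  diag(base) <- 1
  if (any(abs(base) >= 1 & row(base) != col(base))) {
    stop("base_coupling must lie in (-1, 1)")
  }
  structure(list(n_per_group = as.integer(n_per_group), n_regions = r,
                 n_timepoints = as.integer(n_timepoints),
                 base_coupling = base,
                 block_length = as.integer(block_length),
                 volatility = volatility, skew_shift = skew_shift,
                 affected_edges = affected_edges,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

group_field <- function(v, group) {
  unname(v[[if (group == 1L) "pos" else "neg"]])
}

# nearest correlation-like repair: clip eigenvalues and renormalize to unit
# diagonal so the block target is a valid correlation matrix
make_psd_correlation <- function(cc) {
  e <- eigen(cc, symmetric = TRUE)
  if (min(e$values) > 1e-8) return(cc)
  vals <- pmax(e$values, 1e-6)
  m <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(m))
  m / tcrossprod(d)
}

#' Simulate one subject's ROI time series
#'
#' Draws the subject's blocks of correlated Gaussian signal: in block b the
#' target correlation is `base_coupling` perturbed, on the affected edges, by
#' volatility * z_b (plus a skew term when `skew_shift` is nonzero), clipped
#' to (-0.95, 0.95) with a warning when clipping was needed.  Observation
#' noise is added afterwards.  Deterministic given `(spec$seed, subject_index)`.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param group +1 or -1.
#' @param subject_index Integer distinguishing subjects (drives the RNG
#'   stream).
#' @return A [roi_timeseries()].
#' @export
simulate_subject <- function(spec, group, subject_index = 1L) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"), group %in% c(-1L, 1L))
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed((spec$seed * 7919L + as.integer(subject_index) * 104729L) %%
             2147483647L)
  r <- spec$n_regions; m <- spec$n_timepoints
  vol <- group_field(spec$volatility, group)
  skw <- group_field(spec$skew_shift, group)
  n_blocks <- ceiling(m / spec$block_length)
  clipped <- FALSE
  rows <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    cc <- spec$base_coupling
    for (e in seq_len(nrow(spec$affected_edges))) {
      i <- spec$affected_edges[e, 1]; j <- spec$affected_edges[e, 2]
      z <- stats::rnorm(1)
      delta <- vol * z + skw * (z^2 - 1) / sqrt(2)
      val <- cc[i, j] + delta
      if (abs(val) > 0.95) {
        clipped <- TRUE
        val <- sign(val) * 0.95
      }
      cc[i, j] <- cc[j, i] <- val
    }
    cc <- make_psd_correlation(cc)
    len <- min(spec$block_length, m - (b - 1L) * spec$block_length)
    z <- matrix(stats::rnorm(len * r), len, r)
    rows[[b]] <- z %*% chol(cc)
  }
  x <- do.call(rbind, rows)
  if (spec$noise_sd > 0) {
    x <- x + spec$noise_sd * matrix(stats::rnorm(length(x)), nrow(x), ncol(x))
  }
  if (clipped) {
    warning("some requested correlations fell outside (-0.95, 0.95) and were clipped")
  }
  roi_timeseries(x, subject_id = sprintf("sub_%s%03d",
                                         if (group == 1L) "p" else "n",
                                         subject_index))
}

#' Simulate a full two-group cohort
#'
#' Generates `n_per_group` subjects per label (+1 first, then -1) with
#' independent RNG streams derived from the master seed, and optionally
#' writes the series and a manifest to a directory.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param dir Optional output directory; when given, one CSV per subject and
#'   a `manifest.csv` are written there.
#' @return List with `timeseries` (list of [roi_timeseries()]), `labels`
#'   (+1/-1 vector) and `manifest` (a `cohort_manifest` data frame).
#' @export
simulate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  n <- spec$n_per_group
  groups <- rep(c(1L, -1L), each = n)
  ts_list <- vector("list", 2L * n)
  for (s in seq_along(groups)) {
    ts_list[[s]] <- simulate_subject(spec, groups[s], subject_index = s)
  }
  ids <- vapply(ts_list, function(t) t$subject_id, character(1))
  paths <- paste0(ids, ".csv")
  manifest <- data.frame(subject_id = ids, label = groups, path = paths,
                         stringsAsFactors = FALSE)
  class(manifest) <- c("cohort_manifest", "data.frame")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (s in seq_along(ts_list)) {
      write_timeseries(ts_list[[s]], file.path(dir, paths[s]))
    }
    write_manifest(manifest, file.path(dir, "manifest.csv"))
  }
  list(timeseries = ts_list, labels = groups, manifest = manifest)
}
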