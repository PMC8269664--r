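#' Build the high-order FC network Ho(d) from a moment network
#'
#' The i-th row of CM(d) is region i's moment profile — the order-d
#' fluctuation features of its dynamic FC with every region.  Ho(d) is the
#' Pearson correlation between every pair of such profiles, capturing whether
#' regions whose connectivity fluctuates alike (in variance, skewness,
#' kurtosis, ...) form a higher-level interaction pattern.
#'
#' By default the full row participates, including the degenerate diagonal
#' entry (a shared constant for d >= 2); set `include_diagonal = FALSE` to
#' correlate rows with both self entries of each pair removed.
#'
#' @param cm A [network_matrix()] of kind `"cm"` (R >= 3).
#' @param include_diagonal Logical; include the diagonal entries of CM(d) in
#'   the row profiles (default `TRUE`).
#' @return A [network_matrix()] of kind `"ho"` with the same `order_d`.
#' @export
build_hofcn <- function(cm, include_diagonal = TRUE) {
  stopifnot(inherits(cm, "network_matrix"))
  if (!identical(network_kind(cm), "cm")) {
    stop("build_hofcn expects a moment network (kind 'cm'), got '",
         network_kind(cm), "'")
  }
  r <- nrow(cm)
  if (r < 3L) stop("need at least 3 regions to correlate moment profiles")
  v <- unclass(cm)
  if (include_diagonal) {
    h <- row_profile_cor(t(v))
  } else {
    # drop both self entries of each pair so the compared profiles align
    h <- matrix(1, r, r)
    for (i in seq_len(r - 1L)) {
      for (j in (i + 1L):r) {
        keep <- setdiff(seq_len(r), c(i, j))
        h[i, j] <- h[j, i] <- pair_cor(v[i, keep], v[j, keep])
      }
    }
  }
  nz <- attr(h, "n_zero_variance")
  if (!is.null(nz) && nz > 0L) {
    warning(sprintf(
      "%d constant moment profiles; their high-order correlations were set to 0",
      nz))
  }
  attr(h, "n_zero_variance") <- NULL
  net <- network_matrix(h, kind = "ho", order_d = network_order(cm))
  attr(net, "spec") <- attr(cm, "spec")
  net
}

# correlation matrix of the columns of x with the zero-variance-row -> 0
# convention (diagonal stays 1)
row_profile_cor <- function(x) {
  cc <- safe_cor(x)
  nz <- attr(cc, "n_undefined")
  attr(cc, "n_undefined") <- NULL
  attr(cc, "n_zero_variance") <- nz
  cc
}

pair_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Build every network for one subject in a single pass
#'
#' Convenience orchestration: one sliding-window pass produces the dynamic
#' network, then the static C-FCN and RMS baselines plus CM(d) and Ho(d) for
#' every requested order.  Outputs are identical to calling the stage
#' functions independently.
#'
#' @param ts A [roi_timeseries()].
#' @param spec A [sliding_window_spec()].
#' @param orders Integer vector of moment orders (possibly empty, in which
#'   case only the baselines are produced).
#' @param include_diagonal Passed to [build_hofcn()].
#' @return A list with elements `cfcn`, `rms`, `lodfcn`, `cm` (named list by
#'   order) and `ho` (named list by order).
#' @export
build_all_networks <- function(ts, spec, orders = 1:10,
                               include_diagonal = TRUE) {
  dcn <- build_lodfcn(ts, spec)
  orders <- as.integer(orders)
  cm <- ho <- stats::setNames(vector("list", length(orders)),
                              as.character(orders))
  for (d in orders) {
    cm[[as.character(d)]] <- build_cmfcn(dcn, d)
    ho[[as.character(d)]] <- build_hofcn(cm[[as.character(d)]],
                                         include_diagonal = include_diagonal)
  }
  list(cfcn = build_cfcn(ts), rms = build_rmsfcn(dcn), lodfcn = dcn,
       cm = cm, ho = ho)
}
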