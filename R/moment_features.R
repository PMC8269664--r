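#' Order-d central-moment feature of an edge FC series
#'
#' For a windowed correlation series rho(1..K) the order-d feature is the
#' signed d-th root of the averaged centered power sum
#' S = (1/K) * sum_k (rho(k) - mean(rho))^d, i.e. sign(S) * |S|^(1/d).
#' The population 1/K normalization is used.  At d = 1 the centered sum is
#' identically zero, so the arithmetic mean of the series is returned instead.
#' The signed root keeps odd-order features real and preserves the sign of the
#' skew.
#'
#' The K values are sorted before any accumulation, so the result is exactly
#' invariant (bit for bit) to any permutation of the windows — the defining
#' property that removes the chronological-order sensitivity of dynamic FC.
#'
#' @param series Numeric vector of K windowed correlations.
#' @param d Moment order, integer >= 1.
#' @return A single numeric value.
#' @export
central_moment <- function(series, d) {
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop("moment order d must be a positive integer")
  k <- length(series)
  if (d >= 2L && k < 2L) {
    stop("degenerate window count: need K >= 2 for central moments of order >= 2")
  }
  if (k < 1L) stop("empty series")
  xs <- sort(series, method = "radix")
  if (d == 1L) return(sum(xs) / k)
  m <- sum(xs) / k
  s <- sum((xs - m)^d) / k
  sign(s) * abs(s)^(1 / d)
}

#' Build the order-d central-moment FC network CM(d)
#'
#' Applies [central_moment()] to every edge's windowed correlation series,
#' producing the R x R matrix CM(d) whose i-th row is the moment profile of
#' region i (its order-d fluctuation feature against every other region).
#' The diagonal self-series is constantly 1, so the diagonal of CM(1) is 1
#' and the diagonal of CM(d >= 2) is 0.
#'
#' @param dcn A `dynamic_connectivity` object with K >= 2 windows.
#' @param d Moment order in 1..10 (larger values are accepted).
#' @return A [network_matrix()] of kind `"cm"` with `order_d = d`.
#' @export
build_cmfcn <- function(dcn, d) {
  stopifnot(inherits(dcn, "dynamic_connectivity"))
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop("moment order d must be a positive integer")
  dims <- dim(dcn$windows)
  r <- dims[1]; K <- dims[3]
  if (d >= 2L && K < 2L) {
    stop("degenerate window count: need K >= 2 windows for d >= 2")
  }
  # edge series as columns of a K x R^2 matrix; sorted columns make every
  # downstream sum independent of window order
  x <- matrix(aperm(dcn$windows, c(3L, 1L, 2L)), nrow = K)
  xs <- apply(x, 2L, sort, method = "radix")
  if (K == 1L) xs <- matrix(xs, nrow = 1L)
  mu <- colSums(xs) / K
  if (d == 1L) {
    vals <- mu
  } else {
    s <- colSums((xs - rep(mu, each = K))^d) / K
    vals <- sign(s) * abs(s)^(1 / d)
  }
  cm <- matrix(vals, r, r)
  stopifnot(isTRUE(all.equal(diag(cm), rep(if (d == 1L) 1 else 0, r),
                             tolerance = 1e-12)))
  net <- network_matrix(cm, kind = "cm", order_d = d)
  attr(net, "spec") <- dcn$spec
  net
}

#' Root-mean-square of an edge FC series
#'
#' @param series Numeric vector of K windowed correlations.
#' @return sqrt(mean(series^2)).
#' @export
rms_edge <- function(series) {
  if (length(series) < 1L) stop("empty series")
  xs <- sort(series, method = "radix")
  sqrt(sum(xs^2) / length(xs))
}

#' Build the RMS baseline network from a dynamic FC network
#'
#' Per-edge root-mean-square of the windowed correlation series; the
#' comparison feature set for moment-based networks.  Diagonal is 1 (RMS of
#' the constant self-correlation).
#'
#' @param dcn A `dynamic_connectivity` object.
#' @return A [network_matrix()] of kind `"rms"`.
#' @export
build_rmsfcn <- function(dcn) {
  stopifnot(inherits(dcn, "dynamic_connectivity"))
  dims <- dim(dcn$windows)
  r <- dims[1]; K <- dims[3]
  x <- matrix(aperm(dcn$windows, c(3L, 1L, 2L)), nrow = K)
  vals <- sqrt(colSums(x^2) / K)
  net <- network_matrix(matrix(vals, r, r), kind = "rms")
  attr(net, "spec") <- dcn$spec
  net
}
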