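test_that("window segmentation follows K = floor((M - W)/s) + 1", {
  seg <- window_segments(170, sliding_window_spec(30, 2))
  expect_equal(nrow(seg), 71)
  expect_equal(seg$start[1], 1)
  expect_equal(seg$end[1], 30)
  expect_equal(seg$start[71], 141)
  expect_equal(seg$end[71], 170)

  seg1 <- window_segments(10, sliding_window_spec(10, 3))
  expect_equal(nrow(seg1), 1)
  expect_equal(c(seg1$start, seg1$end), c(1, 10))

  # trailing partial window is dropped
  seg2 <- window_segments(11, sliding_window_spec(10, 3))
  expect_equal(nrow(seg2), 1)

  expect_error(window_segments(9, sliding_window_spec(10, 2)), "exceeds")
  expect_error(sliding_window_spec(10, 0), "s must be")
  expect_error(sliding_window_spec(0, 2), "W must be")
})

test_that("perfectly dependent regions give windowed correlations of +/-1", {
  set.seed(5)
  base <- rnorm(40)
  x <- cbind(base, base, -base)
  ts <- roi_timeseries(x, "dep")
  dcn <- build_lodfcn(ts, sliding_window_spec(10, 5))
  K <- dim(dcn$windows)[3]
  for (k in seq_len(K)) {
    expect_equal(dcn$windows[1, 2, k], 1, tolerance = 1e-12)
    expect_equal(dcn$windows[1, 3, k], -1, tolerance = 1e-12)
  }
})

test_that("windowed correlations match the brute-force Pearson oracle", {
  set.seed(17)
  for (rep in 1:3) {
    M <- sample(20:50, 1); R <- sample(3:6, 1)
    W <- sample(8:15, 1); s <- sample(2:6, 1)
    ts <- rand_ts(M, R)
    dcn <- build_lodfcn(ts, sliding_window_spec(W, s))
    oracle <- naive_lodfcn(ts$values, W, s)
    expect_equal(dim(dcn$windows)[3], length(oracle))
    for (k in seq_along(oracle)) {
      expect_lt(max(abs(dcn$windows[, , k] - oracle[[k]])), 1e-12)
    }
  }
})

test_that("static network equals the single full-length window", {
  ts <- rand_ts(40, 5, seed = 23)
  cf <- build_cfcn(ts)
  dcn <- build_lodfcn(ts, sliding_window_spec(40, 7))
  expect_equal(dim(dcn$windows)[3], 1)
  expect_equal(unclass(cf), dcn$windows[, , 1], ignore_attr = TRUE,
               tolerance = 1e-15)
  expect_lt(max(abs(unclass(cf) - naive_cor_matrix(ts$values))), 1e-12)
  expect_identical(attr(cf, "kind"), "static")
})

test_that("correlations are invariant to a common location shift", {
  ts <- rand_ts(30, 4, seed = 31)
  shifted <- roi_timeseries(ts$values + 7.5, "shifted")
  spec <- sliding_window_spec(10, 4)
  expect_equal(build_lodfcn(ts, spec)$windows,
               build_lodfcn(shifted, spec)$windows, tolerance = 1e-12)
})

test_that("a region constant within a window yields 0 with a warning", {
  x <- matrix(rnorm(40), 20, 2)
  x <- cbind(x, c(rep(1, 10), rnorm(10)))
  ts <- roi_timeseries(x, "const")
  expect_warning(dcn <- build_lodfcn(ts, sliding_window_spec(10, 10)),
                 "zero variance")
  expect_equal(dcn$windows[1, 3, 1], 0)
  expect_equal(dcn$windows[3, 3, 1], 1)
  expect_false(any(dcn$windows[, , 2] == 0))
})

test_that("every window is symmetric with unit diagonal and entries in [-1,1]", {
  set.seed(41)
  for (rep in 1:5) {
    ts <- rand_ts(sample(20:40, 1), sample(3:6, 1))
    dcn <- build_lodfcn(ts, sliding_window_spec(10, 3))
    for (k in seq_len(dim(dcn$windows)[3])) {
      w <- dcn$windows[, , k]
      expect_lt(max(abs(w - t(w))), 1e-12)
      expect_equal(diag(w), rep(1, ncol(w)))
      expect_true(all(abs(w) <= 1 + 1e-12))
    }
  }
})

test_that("edge series extraction is symmetric and matches stored windows", {
  ts <- rand_ts(40, 4, seed = 43)
  dcn <- build_lodfcn(ts, sliding_window_spec(10, 5))
  K <- dim(dcn$windows)[3]
  expect_equal(edge_series(dcn, 2, 2), rep(1, K))
  expect_identical(edge_series(dcn, 1, 3), edge_series(dcn, 3, 1))
  expect_equal(edge_series(dcn, 1, 3),
               vapply(seq_len(K), function(k) dcn$windows[1, 3, k],
                      numeric(1)))
  expect_error(edge_series(dcn, 0, 2), "out of range")
  expect_error(edge_series(dcn, 1, 5), "out of range")
})

test_that("block interaction averages match exhaustive enumeration", {
  # constant off-diagonal network: every block mean is that constant
  v <- matrix(0.4, 4, 4); diag(v) <- 1
  net <- network_matrix(v, "static")
  part <- region_partition(c("A", "A", "B", "B"))
  blk <- block_interaction(net, part)
  expect_equal(unclass(blk), matrix(0.4, 2, 2), ignore_attr = TRUE)

  # single system: mean off-diagonal
  one <- block_interaction(net, region_partition(rep("all", 4)))
  expect_equal(as.numeric(one), 0.4)

  # hand-filled network against brute-force averages
  set.seed(47)
  a <- matrix(rnorm(16), 4); vv <- (a + t(a)) / 2; diag(vv) <- 1
  net2 <- network_matrix(vv, "static")
  blk2 <- block_interaction(net2, part)
  idxA <- 1:2; idxB <- 3:4
  within_A <- mean(c(vv[1, 2], vv[2, 1]))
  between <- mean(vv[idxA, idxB])
  expect_equal(blk2["A", "A"], within_A)
  expect_equal(blk2["B", "B"], mean(c(vv[3, 4], vv[4, 3])))
  expect_equal(blk2["A", "B"], between)
  expect_equal(blk2["A", "B"], blk2["B", "A"])

  expect_error(block_interaction(net2, region_partition(c("A", "B", "B", "B"))),
               "empty block")
})
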