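# Independent brute-force oracles, written from the defining formulas with
# naive loops so they share no code path with the package implementation.

# textbook Pearson r from raw sums
naive_pearson <- function(x, y) {
  n <- length(x)
  sx <- 0; sy <- 0; sxy <- 0; sxx <- 0; syy <- 0
  for (t in seq_len(n)) {
    sx <- sx + x[t]; sy <- sy + y[t]
    sxy <- sxy + x[t] * y[t]
    sxx <- sxx + x[t]^2; syy <- syy + y[t]^2
  }
  num <- n * sxy - sx * sy
  den <- sqrt(n * sxx - sx^2) * sqrt(n * syy - sy^2)
  if (den == 0) return(0)
  num / den
}

naive_cor_matrix <- function(x) {
  r <- ncol(x)
  out <- diag(1, r)
  for (i in seq_len(r)) {
    for (j in seq_len(r)) {
      if (i != j) out[i, j] <- naive_pearson(x[, i], x[, j])
    }
  }
  out
}

# per-segment correlation stacks, straight from the K = (M-W)/s + 1 formula
naive_lodfcn <- function(values, W, s) {
  M <- nrow(values)
  K <- (M - W) %/% s + 1
  lapply(seq_len(K), function(k) {
    rows <- ((k - 1) * s + 1):((k - 1) * s + W)
    naive_cor_matrix(values[rows, , drop = FALSE])
  })
}

# d-th central-moment feature: signed d-th root of the 1/K-averaged centered
# power sum; plain mean at d = 1
naive_central_moment <- function(v, d) {
  K <- length(v)
  mu <- sum(v) / K
  if (d == 1) return(mu)
  s <- 0
  for (k in seq_len(K)) s <- s + (v[k] - mu)^d
  s <- s / K
  sign(s) * abs(s)^(1 / d)
}

naive_cm <- function(window_list, d) {
  r <- nrow(window_list[[1]])
  out <- matrix(0, r, r)
  for (i in seq_len(r)) {
    for (j in seq_len(r)) {
      v <- vapply(window_list, function(w) w[i, j], numeric(1))
      out[i, j] <- naive_central_moment(v, d)
    }
  }
  out
}

naive_ho <- function(cm, include_diagonal = TRUE) {
  r <- nrow(cm)
  out <- diag(1, r)
  for (i in seq_len(r)) {
    for (j in seq_len(r)) {
      if (i == j) next
      if (include_diagonal) {
        a <- cm[i, ]; b <- cm[j, ]
      } else {
        keep <- setdiff(seq_len(r), c(i, j))
        a <- cm[i, keep]; b <- cm[j, keep]
      }
      out[i, j] <- naive_pearson(a, b)
    }
  }
  out
}

rand_ts <- function(M, R, seed = NULL, subject_id = "t") {
  if (!is.null(seed)) set.seed(seed)
  roi_timeseries(matrix(rnorm(M * R), M, R), subject_id = subject_id)
}

# assemble a dynamic_connectivity object directly from a window array,
# bypassing build_lodfcn, for tests that need designed edge series
dcn_from_array <- function(arr, W = 10, s = 2, subject_id = "synthetic") {
  structure(list(windows = arr, spec = sliding_window_spec(W, s),
                 subject_id = subject_id),
            class = "dynamic_connectivity")
}

# symmetric window array whose (i,j) edge series are prescribed
dcn_from_edges <- function(R, K, edge_fun) {
  arr <- array(1, dim = c(R, R, K))
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      v <- edge_fun(i, j)
      arr[i, j, ] <- v
      arr[j, i, ] <- v
    }
  }
  dcn_from_array(arr)
}

write_cohort_csvs <- function(dir, n_asd = 3, n_nc = 3, M = 20, R = 4,
                              seed = 1) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- c(paste0("asd", seq_len(n_asd)), paste0("nc", seq_len(n_nc)))
  labels <- c(rep("ASD", n_asd), rep("NC", n_nc))
  for (id in ids) {
    write.table(matrix(rnorm(M * R), M, R), file.path(dir, paste0(id, ".csv")),
                sep = ",", row.names = FALSE, col.names = FALSE)
  }
  man <- data.frame(subject_id = ids, label = labels,
                    path = paste0(ids, ".csv"))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  file.path(dir, "manifest.csv")
}
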