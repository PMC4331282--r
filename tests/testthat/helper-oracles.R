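# Independent brute-force oracles used to freeze expected values.

# Direct O(n*k) causal discrete convolution, y[i] = sum_k g[k+1] * x[i-k].
oracle_convolve <- function(x, g) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    kmax <- min(i, length(g))
    y[i] <- sum(g[seq_len(kmax)] * x[i - seq_len(kmax) + 1])
  }
  y
}

# Rank-sum (Mann-Whitney W) by direct pair counting.
oracle_ranksum_W <- function(x, y) {
  w <- 0
  for (xi in x) for (yj in y) w <- w + (xi > yj) + 0.5 * (xi == yj)
  w
}

# Longest contiguous in-plume dwell (seconds) by explicit scanning.
oracle_max_dwell <- function(inside, dt) {
  best <- 0L; cur <- 0L
  for (v in inside) {
    cur <- if (v) cur + 1L else 0L
    best <- max(best, cur)
  }
  best * dt
}

# Time in window by explicit counting.
oracle_time_in <- function(time, inside, t0, t1, dt) {
  s <- 0L
  for (i in seq_along(time))
    if (time[i] >= t0 && time[i] < t1 && inside[i]) s <- s + 1L
  s * dt
}

# Exact size of the two-sided rank-sum test at nominal alpha for group sizes
# m, n (probability under the null that p <= alpha), via the exact Wilcoxon
# distribution.
oracle_ranksum_size <- function(m, n, alpha = 0.05) {
  ws <- 0:(m * n)
  pr <- stats::dwilcox(ws, m, n)
  pvals <- vapply(ws, function(w) {
    lo <- stats::pwilcox(w, m, n)
    hi <- 1 - stats::pwilcox(w - 1, m, n)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  sum(pr[pvals <= alpha])
}

make_heading <- function(heading, dt = 0.1, plume = 180, fly = "f1",
                         group = "g") {
  heading_trace((seq_along(heading) - 1) * dt, heading, plume,
                fly_id = fly, group = group)
}
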