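# Independent oracles used across the suite. Each re-derives the quantity by
# a different route than the package implementation.

# Penalized smoothing spline by direct dense solve: the roughness matrix is
# built from stats::splinefun natural interpolants of unit vectors, with
# exact Simpson quadrature of the (piecewise-linear) second-derivative
# products, and the quadratic objective minimized by a generic linear solve.
oracle_csaps <- function(x, y, p, w = rep(1, length(x))) {
  n <- length(x)
  g2 <- lapply(seq_len(n), function(i) {
    e <- numeric(n); e[i] <- 1
    f <- stats::splinefun(x, e, method = "natural")
    function(t) f(t, deriv = 2)
  })
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      tot <- 0
      for (k in seq_len(n - 1)) {
        a <- x[k]; b <- x[k + 1]; m <- (a + b) / 2
        tot <- tot + (b - a) / 6 *
          (g2[[i]](a) * g2[[j]](a) + 4 * g2[[i]](m) * g2[[j]](m) +
             g2[[i]](b) * g2[[j]](b))
      }
      K[i, j] <- K[j, i] <- tot
    }
  }
  solve(p * diag(w, n) + (1 - p) * K, p * w * y)
}

# Holm step-down from its definition: sort, multiply by (m - k + 1),
# running maximum, cap at 1.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (k in seq_len(m)) {
    run <- max(run, (m - k + 1) * p[o[k]])
    adj[o[k]] <- min(1, run)
  }
  adj
}

# Exhaustive application of the two inter-spike-interval rules: repeatedly
# find the FIRST interval < lo and replace the pair with its midpoint,
# restarting from scratch each time; then list every interval > hi.
oracle_isi <- function(times, lo = 0.100, hi = 0.400) {
  t <- sort(times)
  repeat {
    if (length(t) < 2) break
    isi <- diff(t)
    k <- which(isi < lo)[1]
    if (is.na(k)) break
    t <- c(t[seq_len(k - 1)], (t[k] + t[k + 1]) / 2,
           if (k + 1 < length(t)) t[(k + 2):length(t)] else numeric(0))
  }
  bad <- if (length(t) >= 2) which(diff(t) > hi) else integer(0)
  list(beat_times = t,
       invalid = cbind(onset = t[bad], offset = t[bad + 1]))
}

# Mid-rank percentile by counting comparisons, one value at a time.
oracle_percentile <- function(v) {
  n <- length(v)
  sapply(v, function(x) {
    r <- sum(v < x) + (sum(v == x) + 1) / 2   # average rank of x's ties
    100 * (r - 1) / (n - 1)
  })
}

# Recall/precision of detected vs true event times with +-tol matching.
match_beats <- function(detected, truth, tol = 0.010) {
  if (length(truth) == 0) return(c(recall = NA, precision = NA))
  hit <- outer(detected, truth, function(a, b) abs(a - b) < tol)
  c(recall = mean(colSums(hit) > 0),
    precision = if (length(detected)) mean(rowSums(hit) > 0) else NA)
}

# Brute-force convolution of the dense 1500 Hz binary beat series with the
# truncated discrete Gaussian, evaluated at requested output times.
oracle_rate <- function(beat_times, duration_s, t_out, fs = 1500, sigma = 1 / 6) {
  n <- floor(duration_s * fs)
  binary <- numeric(n)
  binary[round(beat_times * fs) + 1] <- binary[round(beat_times * fs) + 1] + 1
  W <- ceiling(4 * sigma * fs)
  kern <- stats::dnorm(seq(-W, W) / fs, sd = sigma)
  kern <- kern / (sum(kern) / fs)
  sapply(t_out, function(t) {
    c0 <- round(t * fs) + 1
    idx <- seq(c0 - W, c0 + W)
    ok <- idx >= 1 & idx <= n
    60 * sum(binary[idx[ok]] * kern[ok])
  })
}
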