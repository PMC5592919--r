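# Brute-force oracles, implemented independently of the package internals.

# Enumerate every candidate interval [i, j] and keep those that are maximal
# motionless runs with span >= min_bout. O(n^2); for small sequences.
oracle_bouts_enumerate <- function(flag, dt, min_bout, t0 = 0) {
  n <- length(flag)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!all(flag[i:j])) next
      left_max <- (i == 1L) || !flag[i - 1L]
      right_max <- (j == n) || !flag[j + 1L]
      if (left_max && right_max && (j - i + 1L) * dt >= min_bout) {
        out[[length(out) + 1L]] <- c(t0 + (i - 1L) * dt, t0 + j * dt)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2], duration = m[, 2] - m[, 1])
}

# Explicit forward scan for maximal runs (independent of rle). For long
# sequences.
oracle_bouts_scan <- function(flag, dt, min_bout, t0 = 0) {
  n <- length(flag)
  starts <- c()
  ends <- c()
  i <- 1L
  while (i <= n) {
    if (flag[i]) {
      j <- i
      while (j < n && flag[j + 1L]) j <- j + 1L
      if ((j - i + 1L) * dt >= min_bout) {
        starts <- c(starts, t0 + (i - 1L) * dt)
        ends <- c(ends, t0 + j * dt)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = as.numeric(starts), end = as.numeric(ends),
             duration = as.numeric(ends) - as.numeric(starts))
}

# Windowed mean per the documented rule: full centered window of `window`
# entries (floor((w-1)/2) before, rest after) when it fits, else the
# symmetric [i - m, i + m] with m = min(i - 1, n - i).
oracle_rolling_mean <- function(x, window) {
  n <- length(x)
  before <- (window - 1L) %/% 2L
  after <- window - 1L - before
  out <- numeric(n)
  for (i in seq_len(n)) {
    m <- min(i - 1L, n - i)
    if (m >= after) {
      idx <- (i - before):(i + after)
    } else {
      idx <- (i - m):(i + m)
    }
    out[i] <- mean(x[idx])
  }
  out
}

# Minimum-likelihood two-sided Fisher p from binomial coefficients only.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  total <- m + n2
  prob <- function(x) {
    choose(m, x) * choose(n2, k - x) / choose(total, k)
  }
  xs <- max(0, k - n2):min(k, m)
  ps <- vapply(xs, prob, 0)
  sum(ps[ps <= prob(a) * (1 + 1e-7)])
}

# All binary sequences of a given length, as a list of logical vectors.
all_binary_seqs <- function(n) {
  if (n == 0L) return(list())
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  lapply(seq_len(nrow(grid)), function(i) as.logical(unlist(grid[i, ])))
}

# Quick random velocity trace for property tests.
random_trace <- function(n, dt = 1, p_sleep = 0.4, id = "r") {
  sleeping <- runif(n) < p_sleep
  v <- ifelse(sleeping, 0, runif(n, 0.05, 0.3))
  velocity_trace(v, dt = dt, animal_id = id)
}
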