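# Independent oracles used across the test files. These deliberately avoid
# the package's computational paths: naive per-term products, bisection,
# exhaustive scans.

# Invert the chi-square(1) survival function by bisection (independent of
# qchisq).
bisect_stat <- function(p, lo = 0, hi = 1e4, tol = 1e-12) {
  f <- function(t) stats::pchisq(t, df = 1, lower.tail = FALSE) - p
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Naive mixture log-likelihood: plain densities, no log-space tricks.
naive_loglik <- function(t, pi0, delta) {
  sum(log(pi0 * stats::dchisq(t, 1) +
            (1 - pi0) * stats::dchisq(t, 1, ncp = delta)))
}

# Naive LFDR by direct evaluation of the defining ratio.
naive_lfdr <- function(t, pi0, delta) {
  num <- pi0 * stats::dchisq(t, 1)
  num / (num + (1 - pi0) * stats::dchisq(t, 1, ncp = delta))
}

# Brute-force likelihood-set membership on an explicit grid: recompute every
# likelihood term naively and threshold against the grid maximum.
naive_likelihood_set <- function(t, pi0_grid, delta_grid, ratio_threshold) {
  ll <- matrix(NA_real_, length(pi0_grid), length(delta_grid))
  for (i in seq_along(pi0_grid))
    for (j in seq_along(delta_grid)) {
      pi0 <- pi0_grid[i]; delta <- delta_grid[j]
      if (pi0 == 0) {
        ll[i, j] <- sum(stats::dchisq(t, 1, ncp = delta, log = TRUE))
      } else if (pi0 == 1) {
        ll[i, j] <- sum(stats::dchisq(t, 1, log = TRUE))
      } else {
        ll[i, j] <- naive_loglik(t, pi0, delta)
      }
    }
  ll - max(ll) >= log(ratio_threshold)
}

# Brute-force two-sample KS D: sup over pooled points of the ECDF gap.
naive_ks_d <- function(a, b) {
  pooled <- sort(unique(c(a, b)))
  max(vapply(pooled, function(x)
    abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

# Small two-group sample: n statistics with null fraction pi0.
sim_stats <- function(n, pi0, delta, seed) {
  set.seed(seed)
  null <- stats::rbinom(n, 1, pi0) == 1
  t <- numeric(n)
  t[null] <- stats::rchisq(sum(null), 1)
  t[!null] <- stats::rchisq(sum(!null), 1, ncp = delta)
  pmax(t, .Machine$double.xmin)
}
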