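# Two-group chi-square mixture: densities, LFDR, likelihood, MLE.
#
# The marginal density of a 1-df association statistic t is modelled as
#   f(t) = pi0 * g0(t) + (1 - pi0) * g_delta(t)
# with g0 the central and g_delta the non-central chi-square(1) density.
# All likelihood work is done in log space: t derived from very small
# p-values makes g0(t) underflow long before the mixture itself does.

#' Two-group mixture parameters
#'
#' Container for the parameters of the central/non-central chi-square(1)
#' two-group model: the prior null probability `pi0` and the non-centrality
#' `delta` of the alternative component, with the box constraints used during
#' fitting.
#'
#' @param pi0 Prior probability that a test is null, in `[0, 1]`.
#' @param delta Non-centrality parameter of the alternative chi-square(1)
#'   distribution, in `[d1, d2]`.
#' @param d1,d2 Lower and upper bounds for `delta` (defaults 0.1 and 50).
#' @return An object of class `mixture_params`.
#' @examples
#' mixture_params(0.9, 5)
#' @export
mixture_params <- function(pi0, delta, d1 = 0.1, d2 = 50) {
  stopifnot(is.numeric(pi0), length(pi0) == 1L, is.finite(pi0),
            is.numeric(delta), length(delta) == 1L, is.finite(delta),
            d1 > 0, d2 > d1)
  if (pi0 < 0 || pi0 > 1)
    stop("pi0 must lie in [0, 1], got ", pi0)
  if (delta < d1 || delta > d2)
    stop("delta must lie in [", d1, ", ", d2, "], got ", delta)
  structure(list(pi0 = pi0, delta = delta, d1 = d1, d2 = d2),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("mixture_params: pi0 = %.6g, delta = %.6g (bounds [%g, %g])\n",
              x$pi0, x$delta, x$d1, x$d2))
  invisible(x)
}

#' Convert p-values to chi-square(1) test statistics
#'
#' Inverts the central chi-square(1) survival function so that the returned
#' statistic has upper-tail probability `p` under the null. This is the
#' z-squared statistic of a two-sided Wald test.
#'
#' @param p Numeric vector of p-values in `(0, 1]`. Exactly-zero or
#'   out-of-range values are rejected here; input sanitisation (clamping of
#'   p = 0 artefacts) belongs to [read_sumstats()].
#' @return Numeric vector of non-negative statistics, strictly decreasing
#'   in `p`.
#' @examples
#' pvalue_to_stat(c(1, 0.05, 0.3173))
#' @export
pvalue_to_stat <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p)))
    stop("p-values must be finite numerics; offending index: ",
         paste(utils::head(which(!is.finite(p)), 5L), collapse = ", "))
  bad <- p <= 0 | p > 1
  if (any(bad))
    stop("p-values must lie in (0, 1]; offending index: ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  stats::qchisq(p, df = 1, lower.tail = FALSE)
}

#' Null density g0: central chi-square with 1 df
#'
#' @param t Numeric vector of non-negative statistics.
#' @param log Return the log density?
#' @return `dchisq(t, 1)`, which has an integrable pole at `t = 0`.
#' @export
null_density <- function(t, log = FALSE) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0")
  stats::dchisq(t, df = 1, log = log)
}

# Log non-central chi-square(1) density, closed form:
#   g_delta(t) = exp(-(t + delta)/2) * cosh(sqrt(delta * t)) / sqrt(2 pi t)
# (the 1-df non-central density in terms of I_{-1/2}). Stable log-cosh keeps
# full relative accuracy over the whole (t, delta) box, including far tails
# where the generic non-central series loses precision.
log_alt_density <- function(t, delta) {
  z <- sqrt(delta * t)
  -0.5 * log(2 * pi * t) - (t + delta) / 2 +
    z + log1p(exp(-2 * z)) - log(2)
}

#' Alternative density g_delta: non-central chi-square with 1 df
#'
#' Evaluated in closed form,
#' `g_delta(t) = exp(-(t + delta)/2) cosh(sqrt(delta t)) / sqrt(2 pi t)`,
#' which keeps full relative accuracy in the far tails where generic
#' non-central series evaluations degrade.
#'
#' @param t Numeric vector of non-negative statistics.
#' @param delta Non-centrality parameter; must lie in `[d1, d2]`.
#' @param d1,d2 Bounds on `delta` (defaults 0.1, 50).
#' @param log Return the log density?
#' @export
alt_density <- function(t, delta, d1 = 0.1, d2 = 50, log = FALSE) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0")
  if (length(delta) != 1L || !is.finite(delta) || delta < d1 || delta > d2)
    stop("delta must lie in [", d1, ", ", d2, "], got ", delta)
  ld <- log_alt_density(t, delta)
  if (log) ld else exp(ld)
}

# log(exp(a) + exp(b)) elementwise, safe for -Inf inputs
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[m == -Inf] <- -Inf
  out
}

# Vectorised LFDR at explicit (pi0, delta); internal workhorse.
lfdr_at <- function(t, pi0, delta) {
  if (pi0 >= 1) return(rep(1, length(t)))
  if (pi0 <= 0) return(rep(0, length(t)))
  lg0 <- stats::dchisq(t, df = 1, log = TRUE)
  lgd <- log_alt_density(t, delta)
  # psi = 1 / (1 + exp(log((1-pi0)/pi0) + lgd - lg0))
  stats::plogis(log(pi0) - log1p(-pi0) + lg0 - lgd)
}

#' Local false discovery rate under the two-group model
#'
#' Evaluates `psi(t) = pi0 g0(t) / (pi0 g0(t) + (1 - pi0) g_delta(t))`, the
#' posterior probability that a test with statistic `t` is null.
#'
#' @param t Numeric vector of strictly positive statistics (the g0 pole at 0
#'   is never evaluated: statistics derived from p < 1 are positive).
#' @param params A [mixture_params()] object.
#' @return Numeric vector in `[0, 1]`, non-increasing in `t` and
#'   non-decreasing in `pi0`.
#' @examples
#' lfdr(pvalue_to_stat(0.001), mixture_params(0.9, 10))
#' @export
lfdr <- function(t, params) {
  stopifnot(inherits(params, "mixture_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    stop("t must be finite and > 0 (offending index: ",
         paste(utils::head(which(!(is.finite(t) & t > 0)), 5L),
               collapse = ", "), ")")
  lfdr_at(t, params$pi0, params$delta)
}

#' Mixture log-likelihood
#'
#' `sum_i log(pi0 g0(t_i) + (1 - pi0) g_delta(t_i))`, accumulated in log
#' space so that extreme statistics (tiny p-values) do not underflow.
#'
#' @param t Numeric vector of strictly positive statistics; non-empty.
#' @param params A [mixture_params()] object.
#' @return A finite scalar log-likelihood.
#' @export
log_likelihood <- function(t, params) {
  stopifnot(inherits(params, "mixture_params"))
  if (length(t) == 0L) stop("empty statistic collection")
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    stop("t must be finite and > 0 (offending index: ",
         paste(utils::head(which(!(is.finite(t) & t > 0)), 5L),
               collapse = ", "), ")")
  ll <- loglik_terms(stats::dchisq(t, df = 1, log = TRUE), t,
                     params$pi0, params$delta)
  if (!is.finite(ll))
    stop("non-finite log-likelihood term encountered")
  ll
}

# Sum of log mixture terms given precomputed log g0; recomputes g_delta.
loglik_terms <- function(lg0, t, pi0, delta) {
  lgd <- log_alt_density(t, delta)
  sum(logsumexp2(log(pi0) + lg0, log1p(-pi0) + lgd))
}

# Log-likelihood evaluated over a (pi0, delta) grid.
# Returns a length(pi0_grid) x length(delta_grid) matrix. Work is grouped by
# delta so each non-central density vector is computed once.
grid_loglik <- function(t, pi0_grid, delta_grid) {
  lg0 <- stats::dchisq(t, df = 1, log = TRUE)
  lp0 <- log(pi0_grid)
  lp1 <- log1p(-pi0_grid)
  out <- matrix(NA_real_, nrow = length(pi0_grid), ncol = length(delta_grid))
  for (j in seq_along(delta_grid)) {
    lgd <- log_alt_density(t, delta_grid[j])
    A <- outer(lg0, lp0, "+")
    B <- outer(lgd, lp1, "+")
    m <- pmax(A, B)
    L <- m + log(exp(A - m) + exp(B - m))
    L[m == -Inf] <- -Inf
    out[, j] <- colSums(L)
  }
  out
}

#' Maximum-likelihood fit of the two-group mixture
#'
#' Maximises the mixture log-likelihood over the box
#' `[0, 1] x [d1, d2]` by multi-start bounded quasi-Newton optimisation
#' (the likelihood is nearly flat in `delta` when `pi0` is close to 1, so a
#' single start is unreliable), followed by a grid dominance check: if any
#' point of a verification grid beats the best local optimum, optimisation is
#' restarted there.
#'
#' @param t Numeric vector of strictly positive statistics.
#' @param d1,d2 Bounds on the non-centrality parameter.
#' @param min_n Minimum number of statistics required (default 100); fitting
#'   a two-parameter mixture on fewer is refused so that callers fall back to
#'   a larger reference class.
#' @param starts Matrix or data.frame of starting values with columns
#'   `pi0`, `delta`; default is the cross of pi0 in {0.5, 0.8, 0.9, 0.99}
#'   and delta in {1, 5, 20}.
#' @param grid_check Dimensions `c(n_pi0, n_delta)` of the verification grid
#'   (default `c(50, 50)`), or `NULL` to skip it.
#' @return An object of class `mixture_fit`: fields `params`
#'   ([mixture_params()]), `loglik`, `n`, `converged`, `at_boundary`.
#' @export
fit_mle <- function(t, d1 = 0.1, d2 = 50, min_n = 100,
                    starts = NULL, grid_check = c(50, 50)) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    stop("t must be finite and > 0")
  n <- length(t)
  if (n < min_n)
    stop("too few observations: ", n, " statistics, minimum is ", min_n)
  if (is.null(starts))
    starts <- expand.grid(pi0 = c(0.5, 0.8, 0.9, 0.99),
                          delta = c(1, 5, 20))
  starts <- as.matrix(starts[, c("pi0", "delta"), drop = FALSE])

  lg0 <- stats::dchisq(t, df = 1, log = TRUE)
  negll <- function(par) {
    # clamp so finite-difference gradient probes never leave the box
    pi0 <- min(max(par[1L], 0), 1)
    delta <- min(max(par[2L], d1), d2)
    -loglik_terms(lg0, t, pi0, delta)
  }
  run_from <- function(par) {
    stats::optim(par, negll, method = "L-BFGS-B",
                 lower = c(0, d1), upper = c(1, d2),
                 control = list(maxit = 200L))
  }

  fits <- apply(starts, 1L, run_from, simplify = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "value"))]]

  if (!is.null(grid_check)) {
    pi0_grid <- seq(0, 1, length.out = grid_check[1L])
    delta_grid <- exp(seq(log(d1), log(d2), length.out = grid_check[2L]))
    gl <- grid_loglik(t, pi0_grid, delta_grid)
    if (max(gl) > -best$value + 1e-6) {
      idx <- arrayInd(which.max(gl), dim(gl))
      refit <- run_from(c(pi0_grid[idx[1L]], delta_grid[idx[2L]]))
      if (refit$value < best$value) best <- refit
    }
  }

  pi0 <- min(max(best$par[1L], 0), 1)
  delta <- min(max(best$par[2L], d1), d2)
  tol <- 1e-6
  structure(list(
    params = mixture_params(pi0, delta, d1 = d1, d2 = d2),
    loglik = -best$value,
    n = n,
    converged = best$convergence == 0L,
    at_boundary = (pi0 < tol || pi0 > 1 - tol ||
                     delta < d1 * (1 + tol) || delta > d2 * (1 - tol))
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "mixture_fit: pi0 = %.4f, delta = %.4g, loglik = %.4f (n = %d)%s%s\n",
    x$params$pi0, x$params$delta, x$loglik, x$n,
    if (x$converged) "" else " [NOT CONVERGED]",
    if (x$at_boundary) " [at boundary]" else ""))
  invisible(x)
}
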