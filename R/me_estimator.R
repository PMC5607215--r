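# Maximum-entropy combination of separate- and combined-class LFDRs.
#
# The separate (annotation) class yields a likelihood set of (pi0, delta)
# pairs whose likelihood ratio against the class MLE exceeds a threshold;
# evaluating the LFDR at every member gives each SNP an interval
# [psi_L, psi_U]. The ME estimate is the point of that interval minimising
# the Bernoulli relative entropy to the combined-class estimate, which is
# operationally a clamp of the combined estimate into the interval.

#' Configuration of the likelihood set
#'
#' @param a Interval strength (default 3). The likelihood-ratio threshold is
#'   `1/2^a` under the default rule (`"half-pow"`, the standard 1/8
#'   likelihood interval at `a = 3`) or `1/(2a)` under `"half-lin"`.
#' @param interval_rule `"half-pow"` (default) or `"half-lin"`; see `a`.
#' @param d1,d2 Bounds on the non-centrality parameter (defaults 0.1, 50).
#' @param grid_pi0 Number of uniform grid points for `pi0` on `[0, 1]`
#'   (default 201).
#' @param grid_delta Number of log-spaced grid points for `delta` on
#'   `[d1, d2]` (default 201).
#' @return An object of class `likelihood_set_config`.
#' @export
likelihood_set_config <- function(a = 3,
                                  interval_rule = c("half-pow", "half-lin"),
                                  d1 = 0.1, d2 = 50,
                                  grid_pi0 = 201L, grid_delta = 201L) {
  interval_rule <- match.arg(interval_rule)
  stopifnot(is.numeric(a), length(a) == 1L, a > 0,
            d1 > 0, d2 > d1, grid_pi0 >= 2L, grid_delta >= 2L)
  ratio_threshold <- switch(interval_rule,
                            "half-pow" = 2^(-a),
                            "half-lin" = 1 / (2 * a))
  if (ratio_threshold <= 0 || ratio_threshold > 1)
    stop("ratio threshold derived from a = ", a, " is outside (0, 1]")
  structure(list(a = a, interval_rule = interval_rule,
                 ratio_threshold = ratio_threshold,
                 d1 = d1, d2 = d2,
                 grid_pi0 = as.integer(grid_pi0),
                 grid_delta = as.integer(grid_delta)),
            class = "likelihood_set_config")
}

#' Likelihood set of the separate reference class
#'
#' Evaluates the class log-likelihood on a (pi0, delta) grid — uniform in
#' `pi0`, log-uniform in `delta` — and keeps every point whose likelihood
#' ratio against the grid maximum is at least `cfg$ratio_threshold`. The
#' fitted MLE itself is appended as an extra member (its ratio against the
#' grid maximum is >= 1), so the set always contains the maximiser.
#'
#' @param t Numeric vector of statistics of the separate class.
#' @param fit A `mixture_fit` for the class, from [fit_mle()]; must have
#'   converged.
#' @param cfg A [likelihood_set_config()].
#' @return An object of class `likelihood_set`: `members` (data.frame with
#'   columns `pi0`, `delta`, `loglik`, `source` = "grid"/"mle"), `ref_loglik`
#'   (the grid maximum), plus the grids and `cfg`.
#' @export
likelihood_set <- function(t, fit, cfg = likelihood_set_config()) {
  stopifnot(inherits(fit, "mixture_fit"),
            inherits(cfg, "likelihood_set_config"))
  if (!fit$converged)
    stop("separate-class fit did not converge; refusing to build the set")
  if (length(t) == 0L) stop("empty statistic collection")

  pi0_grid <- seq(0, 1, length.out = cfg$grid_pi0)
  delta_grid <- exp(seq(log(cfg$d1), log(cfg$d2),
                        length.out = cfg$grid_delta))
  ll <- grid_loglik(t, pi0_grid, delta_grid)
  ref <- max(ll)
  keep <- which(ll - ref >= log(cfg$ratio_threshold), arr.ind = TRUE)
  if (nrow(keep) == 0L)
    stop("internal error: likelihood set is empty")

  members <- data.frame(
    pi0 = pi0_grid[keep[, 1L]],
    delta = delta_grid[keep[, 2L]],
    loglik = ll[keep],
    source = "grid",
    stringsAsFactors = FALSE)
  members <- rbind(members, data.frame(
    pi0 = fit$params$pi0, delta = fit$params$delta,
    loglik = fit$loglik, source = "mle", stringsAsFactors = FALSE))

  structure(list(members = members, ref_loglik = ref,
                 pi0_grid = pi0_grid, delta_grid = delta_grid, cfg = cfg),
            class = "likelihood_set")
}

#' @export
print.likelihood_set <- function(x, ...) {
  g <- x$members$source == "grid"
  cat(sprintf(
    "likelihood_set: %d of %d grid points (threshold %.4g), pi0 in [%.3f, %.3f], delta in [%.3g, %.3g]\n",
    sum(g), length(x$pi0_grid) * length(x$delta_grid),
    x$cfg$ratio_threshold,
    min(x$members$pi0), max(x$members$pi0),
    min(x$members$delta), max(x$members$delta)))
  invisible(x)
}

#' Per-SNP LFDR interval induced by a likelihood set
#'
#' For each statistic, `lo`/`hi` are the min/max of the LFDR over all
#' members of the set. Because the LFDR is monotone increasing in `pi0` for
#' fixed `(t, delta)`, only the smallest and largest `pi0` present for each
#' distinct `delta` can attain the extremes; the scan is restricted to those
#' candidates (exact, not an approximation).
#'
#' @param t Numeric vector of strictly positive statistics.
#' @param lset A [likelihood_set()], or a data.frame of `pi0`, `delta`
#'   members.
#' @return data.frame with columns `lo`, `hi`, one row per statistic.
#' @export
lfdr_interval <- function(t, lset) {
  members <- if (inherits(lset, "likelihood_set")) lset$members else lset
  if (is.null(members) || nrow(members) == 0L)
    stop("empty likelihood set")
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    stop("t must be finite and > 0")

  lo <- rep(1, length(t))
  hi <- rep(0, length(t))
  for (d in unique(members$delta)) {
    p_here <- members$pi0[members$delta == d]
    for (p in c(min(p_here), max(p_here))) {
      psi <- lfdr_at(t, p, d)
      lo <- pmin(lo, psi)
      hi <- pmax(hi, psi)
    }
  }
  data.frame(lo = lo, hi = hi)
}

#' Bernoulli relative entropy between two LFDR values
#'
#' `D(psi, psi_ref) = psi log(psi/psi_ref) + (1-psi) log((1-psi)/(1-psi_ref))`,
#' the Kullback-Leibler divergence between Bernoulli(psi) and
#' Bernoulli(psi_ref). Arguments at exactly 0 or 1 are nudged inward by
#' 1e-12; the ME estimator itself never needs D evaluated (the clamp is its
#' closed form), so this affects diagnostics only.
#'
#' @param psi,psi_ref Numeric vectors in `[0, 1]` (recycled).
#' @return Non-negative divergence; 0 iff `psi == psi_ref`.
#' @export
relative_entropy <- function(psi, psi_ref) {
  if (any(psi < 0 | psi > 1, na.rm = FALSE) ||
      any(psi_ref < 0 | psi_ref > 1) || anyNA(psi) || anyNA(psi_ref))
    stop("arguments must lie in [0, 1]")
  eps <- 1e-12
  psi <- pmin(pmax(psi, eps), 1 - eps)
  psi_ref <- pmin(pmax(psi_ref, eps), 1 - eps)
  psi * log(psi / psi_ref) + (1 - psi) * log((1 - psi) / (1 - psi_ref))
}

#' Maximum-entropy combination of a combined-class LFDR with an interval
#'
#' Returns the point of `[lo, hi]` closest in Bernoulli relative entropy to
#' `psi_combined`; because the divergence is convex with its minimum at
#' `psi_combined`, this is the clamp (elementwise median of `lo`,
#' `psi_combined`, `hi`).
#'
#' @param psi_combined Numeric vector of combined-class LFDR estimates.
#' @param interval A data.frame with columns `lo`, `hi` (as returned by
#'   [lfdr_interval()]), or a numeric length-2 vector `c(lo, hi)`.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' me_combine(0.1, c(0.2, 0.4))  # below the interval -> 0.2
#' @export
me_combine <- function(psi_combined, interval) {
  if (is.numeric(interval) && length(interval) == 2L)
    interval <- data.frame(lo = interval[1L], hi = interval[2L])
  stopifnot(all(c("lo", "hi") %in% names(interval)))
  if (any(interval$lo > interval$hi))
    stop("invalid interval: lo > hi")
  if (any(psi_combined < 0 | psi_combined > 1))
    stop("psi_combined must lie in [0, 1]")
  pmin(pmax(psi_combined, interval$lo), interval$hi)
}

#' ME LFDR estimates for one separate reference class
#'
#' Fits the combined model on all statistics and the separate model on the
#' class statistics, builds the class likelihood set and per-SNP LFDR
#' intervals, and clamps the combined-class estimate into each interval.
#' SNPs outside the class — or every class SNP, when the class is smaller
#' than `min_n` or its fit fails — carry the combined estimate unchanged
#' (`source = "combined-fallback"`).
#'
#' @param stats Named numeric vector of statistics keyed by SNP id (all
#'   panel SNPs).
#' @param class_ids Character vector of SNP ids forming the separate class;
#'   must be a subset of `names(stats)`.
#' @param cfg A [likelihood_set_config()].
#' @param min_n Minimum class size for separate-class fitting (default 100).
#' @param combined_fit Optional precomputed `mixture_fit` on `stats`
#'   (avoids refitting the combined class for every annotation).
#' @return data.frame with one row per panel SNP: `snp_id`, `psi_combined`,
#'   `psi_separate` (NA outside the class), `lo`, `hi`, `psi_me`,
#'   `diff = psi_combined - psi_me`, `source`.
#' @export
estimate_class <- function(stats, class_ids, cfg = likelihood_set_config(),
                           min_n = 100, combined_fit = NULL) {
  if (length(stats) == 0L) stop("empty statistic collection")
  if (is.null(names(stats)) || anyNA(names(stats)))
    stop("stats must be named by snp_id")
  missing_ids <- setdiff(class_ids, names(stats))
  if (length(missing_ids) > 0L)
    stop("class ids absent from the panel: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))

  if (is.null(combined_fit))
    combined_fit <- fit_mle(stats, d1 = cfg$d1, d2 = cfg$d2, min_n = 1)
  psi_c <- lfdr(stats, combined_fit$params)

  out <- data.frame(
    snp_id = names(stats),
    psi_combined = psi_c,
    psi_separate = NA_real_,
    lo = NA_real_,
    hi = NA_real_,
    psi_me = psi_c,
    source = "combined-fallback",
    stringsAsFactors = FALSE)

  in_class <- names(stats) %in% class_ids
  t_s <- stats[in_class]
  separate_ok <- length(t_s) >= min_n
  if (separate_ok) {
    fit_s <- tryCatch(
      fit_mle(t_s, d1 = cfg$d1, d2 = cfg$d2, min_n = min_n),
      error = function(e) NULL)
    separate_ok <- !is.null(fit_s) && fit_s$converged
  }
  if (separate_ok) {
    lset <- likelihood_set(t_s, fit_s, cfg)
    iv <- lfdr_interval(t_s, lset)
    out$psi_separate[in_class] <- lfdr(t_s, fit_s$params)
    out$lo[in_class] <- iv$lo
    out$hi[in_class] <- iv$hi
    out$psi_me[in_class] <- me_combine(psi_c[in_class], iv)
    out$source[in_class] <- "separate-interval"
  }
  out$diff <- out$psi_combined - out$psi_me
  rownames(out) <- NULL
  out
}
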