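# Likelihood set, LFDR intervals, relative entropy, and the ME clamp.

test_that("likelihood_set matches a brute-force grid oracle", {
  t <- sim_stats(200, 0.85, 8, seed = 5)
  fit <- fit_mle(t)
  cfg <- likelihood_set_config(grid_pi0 = 21L, grid_delta = 21L)
  lset <- likelihood_set(t, fit, cfg)
  grid_members <- lset$members[lset$members$source == "grid", ]

  oracle <- naive_likelihood_set(t, lset$pi0_grid, lset$delta_grid,
                                 cfg$ratio_threshold)
  got <- matrix(FALSE, 21L, 21L)
  got[cbind(match(grid_members$pi0, lset$pi0_grid),
            match(grid_members$delta, lset$delta_grid))] <- TRUE
  expect_identical(got, oracle)
  # the MLE is always a member
  expect_true("mle" %in% lset$members$source)
  expect_false(nrow(lset$members) == 0L)
})

test_that("a ratio threshold of 1 keeps exactly the grid argmax", {
  t <- sim_stats(300, 0.9, 10, seed = 6)
  fit <- fit_mle(t)
  # a = 0 under the half-pow rule gives threshold 2^0 = 1
  cfg <- likelihood_set_config(a = 1e-12, grid_pi0 = 21L, grid_delta = 21L)
  lset <- likelihood_set(t, fit, cfg)
  grid_members <- lset$members[lset$members$source == "grid", ]
  expect_equal(nrow(grid_members), 1L)
  expect_equal(grid_members$loglik, lset$ref_loglik)
})

test_that("the likelihood set concentrates as the class grows", {
  cfg <- likelihood_set_config(grid_pi0 = 41L, grid_delta = 41L)
  frac <- vapply(c(1000L, 10000L), function(n) {
    t <- sim_stats(n, 0.8, 10, seed = 21)
    lset <- likelihood_set(t, fit_mle(t), cfg)
    sum(lset$members$source == "grid") / (41 * 41)
  }, numeric(1))
  expect_lt(frac[2], frac[1])
})

test_that("interval-rule options set the documented thresholds", {
  expect_equal(likelihood_set_config(a = 3)$ratio_threshold, 1 / 8)
  expect_equal(
    likelihood_set_config(a = 3, interval_rule = "half-lin")$ratio_threshold,
    1 / 6)
  expect_error(likelihood_set_config(a = -1), "a")
})

test_that("lfdr_interval equals an exhaustive scan over the member set", {
  t <- sim_stats(200, 0.8, 6, seed = 9)
  fit <- fit_mle(t)
  lset <- likelihood_set(t, fit,
                         likelihood_set_config(grid_pi0 = 21L,
                                               grid_delta = 21L))
  probe <- c(0.3, 1, 3.84, 10, 25)
  iv <- lfdr_interval(probe, lset)
  # full scan over every member, no per-delta shortcut
  scan <- sapply(seq_len(nrow(lset$members)), function(k)
    naive_lfdr(probe, lset$members$pi0[k], lset$members$delta[k]))
  expect_equal(iv$lo, apply(scan, 1, min), tolerance = 1e-12)
  expect_equal(iv$hi, apply(scan, 1, max), tolerance = 1e-12)
  expect_true(all(iv$lo <= iv$hi))
  # the separate-class point estimate lies inside every interval
  psi_s <- lfdr(probe, fit$params)
  expect_true(all(iv$lo <= psi_s + 1e-12 & psi_s <= iv$hi + 1e-12))
})

test_that("lfdr_interval handles point sets and rejects empty ones", {
  one <- data.frame(pi0 = 0.9, delta = 5)
  iv <- lfdr_interval(3.84, one)
  expect_equal(iv$lo, iv$hi)
  expect_equal(iv$lo, naive_lfdr(3.84, 0.9, 5), tolerance = 1e-12)
  expect_error(lfdr_interval(3.84, data.frame(pi0 = numeric(0),
                                              delta = numeric(0))),
               "empty")
})

test_that("enlarging a never shrinks any interval", {
  t <- sim_stats(500, 0.85, 8, seed = 14)
  fit <- fit_mle(t)
  probe <- c(0.5, 2, 5, 15)
  prev <- NULL
  for (a in c(1, 3, 6)) {
    cfg <- likelihood_set_config(a = a, grid_pi0 = 41L, grid_delta = 41L)
    iv <- lfdr_interval(probe, likelihood_set(t, fit, cfg))
    if (!is.null(prev)) {
      expect_true(all(iv$lo <= prev$lo + 1e-12))
      expect_true(all(iv$hi >= prev$hi - 1e-12))
    }
    prev <- iv
  }
})

test_that("relative entropy is a convex divergence with known values", {
  expect_equal(relative_entropy(0.3, 0.3), 0, tolerance = 1e-9)
  expect_equal(relative_entropy(0.5, 0.25),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-10)
  expect_equal(relative_entropy(0.5, 0.25), 0.1438, tolerance = 1e-3)
  grid <- seq(0.001, 0.999, length.out = 999)
  d <- relative_entropy(grid, 0.4)
  expect_true(all(d >= 0))
  expect_equal(grid[which.min(d)], 0.4, tolerance = 2e-3)
  # convex: second differences non-negative
  expect_true(all(diff(diff(d)) > -1e-12))
  expect_error(relative_entropy(1.5, 0.5), "\\[0, 1\\]")
  expect_error(relative_entropy(0.5, -0.1), "\\[0, 1\\]")
})

test_that("me_combine is the clamp and the entropy argmin", {
  # the three defining cases
  expect_equal(me_combine(0.3, c(0.2, 0.4)), 0.3)
  expect_equal(me_combine(0.1, c(0.2, 0.4)), 0.2)
  expect_equal(me_combine(0.5, c(0.2, 0.4)), 0.4)
  # random pairs: clamp == median == numeric argmin of relative entropy
  set.seed(31)
  for (i in 1:50) {
    ends <- sort(stats::runif(2))
    c0 <- stats::runif(1)
    got <- me_combine(c0, c(ends[1], ends[2]))
    expect_equal(got, stats::median(c(ends[1], c0, ends[2])))
    grid <- seq(ends[1], ends[2], length.out = 2001)
    expect_lte(abs(got - grid[which.min(relative_entropy(grid, c0))]),
               (ends[2] - ends[1]) / 2000 + 1e-12)
  }
  expect_error(me_combine(0.5, c(0.4, 0.2)), "lo > hi")
  expect_error(me_combine(1.5, c(0.2, 0.4)), "\\[0, 1\\]")
})

test_that("estimate_class collapses to the combined estimate on the full panel", {
  t <- sim_stats(600, 0.85, 9, seed = 18)
  names(t) <- sprintf("rs%04d", seq_along(t))
  cfg <- likelihood_set_config(grid_pi0 = 41L, grid_delta = 41L)
  est <- estimate_class(t, names(t), cfg = cfg)
  expect_equal(nrow(est), length(t))
  expect_true(all(est$source == "separate-interval"))
  # separate data == combined data: psi_C falls inside every interval
  expect_equal(est$psi_me, est$psi_combined, tolerance = 1e-12)
  expect_true(all(est$diff == 0))
})

test_that("small classes fall back to the combined estimate", {
  t <- sim_stats(500, 0.9, 10, seed = 19)
  names(t) <- sprintf("rs%04d", seq_along(t))
  est <- estimate_class(t, names(t)[1:20], min_n = 100)
  in_class <- est$snp_id %in% names(t)[1:20]
  expect_true(all(est$source[in_class] == "combined-fallback"))
  expect_equal(est$psi_me[in_class], est$psi_combined[in_class])
  expect_true(all(is.na(est$psi_separate[in_class])))
})

test_that("estimate_class validates its inputs", {
  t <- sim_stats(200, 0.9, 10, seed = 20)
  names(t) <- sprintf("rs%04d", seq_along(t))
  expect_error(estimate_class(numeric(0), character(0)), "empty")
  expect_error(estimate_class(t, c("nope1", "nope2")), "absent")
})

test_that("enriched classes pull LFDR down for small-p members", {
  n <- 20000L
  t <- c(sim_stats(19000, 0.95, 10, seed = 23),
         sim_stats(1000, 0.7, 10, seed = 24))
  names(t) <- sprintf("rs%05d", seq_len(n))
  class_ids <- names(t)[19001:20000]
  cfg <- likelihood_set_config(grid_pi0 = 101L, grid_delta = 51L)
  est <- estimate_class(t, class_ids, cfg = cfg)
  in_class <- est$snp_id %in% class_ids
  p <- stats::pchisq(t, 1, lower.tail = FALSE)
  sel <- in_class & p[est$snp_id] < 0.01
  expect_gt(sum(sel), 20)
  expect_lt(mean(est$psi_me[sel]), mean(est$psi_combined[sel]))
})
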