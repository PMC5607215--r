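# Synthetic GWAS-like panels with known ground truth.
#
# Emulates the structure the estimator assumes: a large SNP panel with
# MAF >= 0.005, overlapping annotation categories covering known fractions
# of the panel, and a two-group statistic per reference class — null SNPs
# draw a central chi-square(1) statistic, non-null SNPs a non-central one
# with class-specific non-centrality. Enriched categories have smaller pi0
# and/or larger delta than the background.

#' Synthetic panel configuration
#'
#' Defaults describe a coronary-artery-disease-like panel scaled to desk
#' size: a 100,000-SNP panel with background (pi0 = 0.95, delta = 10) and
#' three overlapping enriched categories whose panel fractions mirror the
#' relative sizes of enhancer, H3K9ac and fetal-DHS annotation classes in a
#' 9.45M-variant consortium panel.
#'
#' @param n_snps Panel size (default 1e5).
#' @param overall List `(pi0, delta)` for SNPs outside every category.
#' @param categories List of per-category lists with fields `name`,
#'   `fraction` (of the panel), `pi0`, `delta`, `overlap` (fraction of the
#'   category drawn from previously defined categories' members).
#' @param maf_model List `(shape1, shape2, min, max)`: MAF is
#'   `min + (max - min) * Beta(shape1, shape2)`, skewed toward low
#'   frequencies and bounded below at the consortium inclusion cutoff 0.005.
#' @param n_effective Nominal study sample size used only for the cosmetic
#'   `beta` column (default 184305 = 60801 cases + 123504 controls).
#' @param d1,d2 Bounds on the non-centrality parameter.
#' @param seed Integer seed; the panel is a deterministic function of the
#'   config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_snps = 100000L,
                             overall = list(pi0 = 0.95, delta = 10),
                             categories = list(
                               list(name = "enhancer_like", fraction = 0.043,
                                    pi0 = 0.80, delta = 10, overlap = 0),
                               list(name = "h3k9ac_like", fraction = 0.034,
                                    pi0 = 0.70, delta = 12, overlap = 0.3),
                               list(name = "fetal_dhs_like", fraction = 0.027,
                                    pi0 = 0.90, delta = 8, overlap = 0.2)),
                             maf_model = list(shape1 = 0.5, shape2 = 2.5,
                                              min = 0.005, max = 0.5),
                             n_effective = 184305,
                             d1 = 0.1, d2 = 50,
                             seed = 1L) {
  stopifnot(n_snps >= 1, overall$pi0 >= 0, overall$pi0 <= 1,
            overall$delta >= d1, overall$delta <= d2,
            maf_model$min > 0, maf_model$max <= 0.5,
            maf_model$min < maf_model$max)
  for (cat in categories) {
    if (is.null(cat$name) || !nzchar(cat$name))
      stop("every category needs a name")
    if (cat$fraction <= 0 || cat$fraction > 1)
      stop("category '", cat$name, "': fraction must be in (0, 1]")
    if (cat$pi0 < 0 || cat$pi0 > 1)
      stop("category '", cat$name, "': pi0 must be in [0, 1]")
    if (cat$delta < d1 || cat$delta > d2)
      stop("category '", cat$name, "': delta outside [", d1, ", ", d2, "]")
    if (is.null(cat$overlap)) cat$overlap <- 0
    if (cat$overlap < 0 || cat$overlap >= 1)
      stop("category '", cat$name, "': overlap must be in [0, 1)")
  }
  structure(list(n_snps = as.integer(n_snps), overall = overall,
                 categories = categories, maf_model = maf_model,
                 n_effective = n_effective, d1 = d1, d2 = d2,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate an annotated GWAS-like panel with known truth
#'
#' Category membership is sampled first (with the configured overlap between
#' categories); each SNP then draws its null status from the pi0 of its most
#' specific containing category (smallest panel fraction), falling back to
#' the background parameters outside all categories. Null statistics are
#' central chi-square(1), non-null statistics non-central with the class
#' delta; p-values are the exact chi-square survival probabilities, so the
#' panel is perfectly calibrated by construction. The `beta` column carries
#' a plausible effect size (`|beta| = sqrt(t / (2 maf (1-maf) N))`, random
#' sign) for format fidelity only; no estimator reads it.
#'
#' @param cfg A [synthetic_config()].
#' @return List with elements `snps` (data.frame: `snp_id`, `chrom`, `pos`,
#'   `maf`, `beta`, `p`), `catalog` (an `annotation_catalog`) and `truth`
#'   (data.frame: `snp_id`, `class`, `pi0`, `delta`, `is_null`, `t`).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_snps

  snp_id <- sprintf("rs%08d", seq_len(n))
  chrom <- as.character(sort(sample(1:22, n, replace = TRUE)))
  pos <- stats::ave(seq_len(n), chrom,
                    FUN = function(i) sort(sample.int(2.5e8, length(i))))
  mm <- cfg$maf_model
  maf <- mm$min + (mm$max - mm$min) * stats::rbeta(n, mm$shape1, mm$shape2)

  # category membership with configured overlap against earlier categories
  members <- list()
  union_prev <- integer(0)
  for (cat in cfg$categories) {
    m <- max(1L, round(cat$fraction * n))
    overlap <- if (is.null(cat$overlap)) 0 else cat$overlap
    n_shared <- min(round(overlap * m), length(union_prev))
    shared <- if (n_shared > 0L) sample(union_prev, n_shared) else integer(0)
    fresh_pool <- setdiff(seq_len(n), union_prev)
    fresh <- sample(fresh_pool, m - n_shared)
    idx <- sort(c(shared, fresh))
    members[[cat$name]] <- idx
    union_prev <- union(union_prev, idx)
  }

  # most specific class per SNP: smallest-fraction category containing it
  class <- rep("background", n)
  pi0 <- rep(cfg$overall$pi0, n)
  delta <- rep(cfg$overall$delta, n)
  ord <- order(vapply(cfg$categories, `[[`, numeric(1L), "fraction"),
               decreasing = TRUE)
  for (k in ord) {
    cat <- cfg$categories[[k]]
    idx <- members[[cat$name]]
    class[idx] <- cat$name
    pi0[idx] <- cat$pi0
    delta[idx] <- cat$delta
  }

  is_null <- stats::rbinom(n, 1L, pi0) == 1L
  t <- numeric(n)
  t[is_null] <- stats::rchisq(sum(is_null), df = 1)
  if (any(!is_null)) {
    nn <- which(!is_null)
    t[nn] <- stats::rchisq(length(nn), df = 1, ncp = delta[nn])
  }
  t <- pmax(t, .Machine$double.xmin)  # guard the g0 pole at t = 0
  p <- stats::pchisq(t, df = 1, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)

  beta <- sample(c(-1, 1), n, replace = TRUE) *
    sqrt(t / (2 * maf * (1 - maf) * cfg$n_effective))

  snps <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                     maf = maf, beta = beta, p = p,
                     stringsAsFactors = FALSE)
  truth <- data.frame(snp_id = snp_id, class = class, pi0 = pi0,
                      delta = delta, is_null = is_null, t = t,
                      stringsAsFactors = FALSE)
  catalog <- annotation_catalog(
    lapply(members, function(idx) snp_id[idx]), panel_size = n)
  list(snps = snps, catalog = catalog, truth = truth)
}

#' Oracle LFDR at the true generating parameters
#'
#' Evaluates the two-group LFDR of each SNP at the (pi0, delta) of its
#' generating class — the exact posterior null probability, used as the
#' gold standard in estimator-accuracy and calibration tests.
#'
#' @param truth The `truth` data.frame from [simulate_panel()].
#' @return Numeric vector of oracle LFDRs, one per SNP.
#' @export
truth_lfdr <- function(truth) {
  stopifnot(is.data.frame(truth),
            all(c("t", "pi0", "delta") %in% names(truth)))
  psi <- numeric(nrow(truth))
  key <- paste(truth$pi0, truth$delta)
  for (k in unique(key)) {
    idx <- key == k
    psi[idx] <- lfdr_at(truth$t[idx], truth$pi0[idx][1L],
                        truth$delta[idx][1L])
  }
  psi
}
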