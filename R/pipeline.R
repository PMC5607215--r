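# End-to-end orchestration and stratified reporting: MAF bins and
# significance counts, per-annotation ME estimation, LFDR-change summaries,
# Kolmogorov-Smirnov comparisons between MAF strata, and the small-MAF /
# small-LFDR filter.

#' Minor allele frequency binning
#'
#' Default bins partition (0, 0.5] as <0.001, [0.001, 0.005), [0.005, 0.01),
#' [0.01, 0.05), [0.05, 0.5]: half-open on the right except the last bin,
#' which is closed (its label ">=0.05" fixes the convention).
#'
#' @param edges Strictly increasing interior edges (default
#'   `c(0.001, 0.005, 0.01, 0.05)`).
#' @return An object of class `maf_binning` with `edges` and `labels`.
#' @export
maf_binning <- function(edges = c(0.001, 0.005, 0.01, 0.05)) {
  stopifnot(is.numeric(edges), length(edges) >= 1L, all(diff(edges) > 0),
            all(edges > 0), all(edges < 0.5))
  labels <- c(paste0("<", edges[1L]),
              if (length(edges) > 1L)
                paste0(edges[-length(edges)], "-", edges[-1L]),
              paste0(">=", edges[length(edges)]))
  structure(list(edges = edges, labels = labels), class = "maf_binning")
}

#' Assign each SNP to a MAF bin
#'
#' @param maf Numeric vector in (0, 0.5].
#' @param binning A [maf_binning()].
#' @return Factor of bin labels (levels in bin order).
#' @export
assign_maf_bin <- function(maf, binning = maf_binning()) {
  stopifnot(inherits(binning, "maf_binning"))
  if (any(!is.finite(maf)) || any(maf <= 0 | maf > 0.5))
    stop("maf must lie in (0, 0.5]; offending index: ",
         paste(utils::head(which(!(is.finite(maf) & maf > 0 & maf <= 0.5)),
                           5L), collapse = ", "))
  cut(maf, breaks = c(0, binning$edges, 0.5), labels = binning$labels,
      right = FALSE, include.lowest = TRUE)
}

#' Significance thresholds for the stratified count table
#'
#' @param deviated Threshold for the "P deviated" set — p-values in the tail
#'   of the QQ plot (default 0.0074; 0.001 is the common alternative).
#' @param genomewide Genome-wide significance (default 5e-8).
#' @param genomewide_seq Stricter sequencing-study threshold (default 1e-8).
#' @export
significance_thresholds <- function(deviated = 0.0074, genomewide = 5e-8,
                                    genomewide_seq = 1e-8) {
  stopifnot(deviated > genomewide, genomewide > genomewide_seq,
            genomewide_seq > 0)
  structure(list(deviated = deviated, genomewide = genomewide,
                 genomewide_seq = genomewide_seq),
            class = "significance_thresholds")
}

#' Counts and row percentages of significant SNPs by MAF bin
#'
#' @param snps data.frame with columns `maf`, `p`.
#' @param binning A [maf_binning()].
#' @param thresholds A [significance_thresholds()].
#' @return List of two data.frames, `counts` and `pct` (percentages to two
#'   decimals), with rows `all`, `deviated`, `p<5e-08`, `p<1e-08` and one
#'   column per bin plus `total`.
#' @export
significance_table <- function(snps, binning = maf_binning(),
                               thresholds = significance_thresholds()) {
  stopifnot(is.data.frame(snps), nrow(snps) > 0L,
            all(c("maf", "p") %in% names(snps)))
  bin <- assign_maf_bin(snps$maf, binning)
  sel <- list(
    all = rep(TRUE, nrow(snps)),
    deviated = snps$p < thresholds$deviated,
    "p<5e-08" = snps$p < thresholds$genomewide,
    "p<1e-08" = snps$p < thresholds$genomewide_seq)
  counts <- t(vapply(sel, function(s) table(bin[s]),
                     integer(length(binning$labels))))
  counts <- data.frame(row = names(sel), counts,
                       total = rowSums(counts),
                       check.names = FALSE, stringsAsFactors = FALSE)
  pct <- counts
  tot <- counts$total
  for (j in binning$labels)
    pct[[j]] <- round(ifelse(tot > 0, 100 * counts[[j]] / tot, 0), 2)
  pct$total <- ifelse(tot > 0, 100, 0)
  rownames(counts) <- rownames(pct) <- NULL
  list(counts = counts, pct = pct)
}

#' Run the ME analysis for every annotation category
#'
#' Derives chi-square statistics from the p-values, fits the combined
#' (genome-wide) mixture once, and produces per-annotation ME estimates via
#' [estimate_class()]. Deterministic given inputs and config.
#'
#' @param snps data.frame with columns `snp_id`, `p` (and whatever else the
#'   caller carries along).
#' @param catalog An `annotation_catalog` over the same panel.
#' @param cfg A [likelihood_set_config()].
#' @param min_n Minimum separate-class size (default 100).
#' @return Named list (one element per category, in catalog order) of
#'   [estimate_class()] data.frames; the combined `mixture_fit` is attached
#'   as attribute `combined_fit`.
#' @export
run_me_analysis <- function(snps, catalog, cfg = likelihood_set_config(),
                            min_n = 100) {
  stopifnot(is.data.frame(snps), all(c("snp_id", "p") %in% names(snps)),
            inherits(catalog, "annotation_catalog"))
  stats <- pvalue_to_stat(snps$p)
  stats <- pmax(stats, .Machine$double.xmin)  # p = 1 maps to t = 0
  names(stats) <- snps$snp_id
  combined_fit <- fit_mle(stats, d1 = cfg$d1, d2 = cfg$d2, min_n = 1)
  out <- lapply(names(catalog$categories), function(nm) {
    estimate_class(stats, catalog$categories[[nm]], cfg = cfg,
                   min_n = min_n, combined_fit = combined_fit)
  })
  names(out) <- names(catalog$categories)
  attr(out, "combined_fit") <- combined_fit
  out
}

#' Summary of LFDR changes by p-value stratum
#'
#' For each p-value stratum (p < cutoff) and drop threshold, counts the SNPs
#' whose LFDR decreased by at least the threshold under the ME method
#' (`diff = psi_combined - psi_me >= threshold`), plus quantiles of the
#' change for distribution plots.
#'
#' @param estimates [estimate_class()] data.frame for one annotation.
#' @param p Named numeric vector of p-values keyed by SNP id (or a
#'   data.frame with `snp_id`, `p`).
#' @param p_strata P-value cutoffs defining the strata (default
#'   `c(0.05, 0.01, 0.001)`).
#' @param drop_thresholds Minimum LFDR decreases tallied (default
#'   `c(0.10, 0.20, 0.30)`).
#' @return data.frame with columns `stratum`, `n_stratum`, `threshold`,
#'   `count`, `fraction`; attribute `quantiles` holds per-stratum quartiles
#'   of `diff`.
#' @export
change_summary <- function(estimates, p,
                           p_strata = c(0.05, 0.01, 0.001),
                           drop_thresholds = c(0.10, 0.20, 0.30)) {
  if (is.data.frame(p)) p <- stats::setNames(p$p, p$snp_id)
  stopifnot(all(estimates$snp_id %in% names(p)))
  pv <- p[estimates$snp_id]
  diff <- estimates$diff

  rows <- list()
  qs <- list()
  for (ps in p_strata) {
    in_str <- pv < ps
    n_str <- sum(in_str)
    for (thr in drop_thresholds) {
      cnt <- sum(diff[in_str] >= thr)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = paste0("p<", ps), n_stratum = n_str, threshold = thr,
        count = cnt, fraction = if (n_str > 0) cnt / n_str else 0)
    }
    q <- if (n_str > 0) stats::quantile(diff[in_str], c(0, .25, .5, .75, 1))
         else rep(NA_real_, 5L)
    qs[[length(qs) + 1L]] <- data.frame(
      stratum = paste0("p<", ps), n_stratum = n_str,
      q0 = q[1L], q25 = q[2L], q50 = q[3L], q75 = q[4L], q100 = q[5L],
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "quantiles") <- do.call(rbind, qs)
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum gap between the two empirical CDFs; being rank-based it
#' is invariant under any strictly increasing transform of both samples, so
#' p-values and LFDR estimates give identical results within a fitted class.
#' The p-value is asymptotic.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return An object of class `ks_result`: `d`, `p_value`, `n1`, `n2`.
#' @export
ks_compare <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  kt <- suppressWarnings(stats::ks.test(group_a, group_b, exact = FALSE))
  structure(list(d = unname(kt$statistic), p_value = unname(kt$p.value),
                 n1 = length(group_a), n2 = length(group_b)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("KS two-sample: D = %.4f, p = %.3g (n1 = %d, n2 = %d)\n",
              x$d, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' SNPs with small MAF and small ME LFDR, ordered by LFDR decrease
#'
#' The scatter-data filter: rows with `maf < maf_cut` (strict) and
#' `psi_me < lfdr_cut` (strict), sorted by `diff` descending.
#'
#' @param estimates [estimate_class()] data.frame.
#' @param maf Named numeric vector keyed by SNP id (or data.frame with
#'   `snp_id`, `maf`).
#' @param maf_cut,lfdr_cut Strict upper cutoffs (defaults 0.10, 0.10).
#' @return data.frame `snp_id`, `maf`, `psi_me`, `diff`; possibly 0 rows.
#' @export
top_movers <- function(estimates, maf, maf_cut = 0.10, lfdr_cut = 0.10) {
  if (is.data.frame(maf)) maf <- stats::setNames(maf$maf, maf$snp_id)
  stopifnot(all(estimates$snp_id %in% names(maf)))
  m <- maf[estimates$snp_id]
  keep <- m < maf_cut & estimates$psi_me < lfdr_cut
  out <- data.frame(snp_id = estimates$snp_id[keep], maf = unname(m[keep]),
                    psi_me = estimates$psi_me[keep],
                    diff = estimates$diff[keep], stringsAsFactors = FALSE)
  out <- out[order(-out$diff), , drop = FALSE]
  rownames(out) <- NULL
  out
}
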