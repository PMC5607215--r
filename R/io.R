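# Readers and writers for consortium-style summary statistics, annotation
# files, the per-SNP results table, and flat YAML configs. Delimiters are
# auto-detected on read (tab or comma); output is always tab-delimited.

default_column_map <- c(snp_id = "legendrs", chrom = "chr", pos = "pos",
                        maf = "maf", beta = "beta", p = "p_dgc")

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file (tab or comma, auto-detected), maps the
#' consortium column names onto typed fields, and sanitises the values:
#' p-values of exactly 0 are clamped to the smallest positive double with a
#' warning, p > 1 rounding artefacts are clamped to 1, and rows with
#' missing or unusable p/maf/pos are dropped and counted.
#'
#' @param path File path.
#' @param column_map Named character vector mapping internal field names
#'   (`snp_id`, `chrom`, `pos`, `maf`, `beta`, `p`) to file headers;
#'   defaults to the consortium-style names (`legendrs`, `chr`, `pos`,
#'   `maf`, `beta`, `p_dgc`). `beta` is optional in the file.
#' @return data.frame of typed records in file order, with attribute
#'   `report` (named integer vector of dropped-row counts by reason).
#' @export
read_sumstats <- function(path, column_map = default_column_map) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "auto", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  mandatory <- c("snp_id", "chrom", "pos", "maf", "p")
  have <- column_map[mandatory] %in% names(dt)
  if (!all(have))
    stop("missing mandatory column(s) ",
         paste(column_map[mandatory][!have], collapse = ", "),
         "; available headers: ", paste(names(dt), collapse = ", "))

  out <- data.frame(
    snp_id = as.character(dt[[column_map[["snp_id"]]]]),
    chrom = as.character(dt[[column_map[["chrom"]]]]),
    pos = suppressWarnings(as.integer(dt[[column_map[["pos"]]]])),
    maf = suppressWarnings(as.numeric(dt[[column_map[["maf"]]]])),
    beta = if (column_map[["beta"]] %in% names(dt))
      suppressWarnings(as.numeric(dt[[column_map[["beta"]]]]))
    else NA_real_,
    p = suppressWarnings(as.numeric(dt[[column_map[["p"]]]])),
    stringsAsFactors = FALSE)

  report <- c(missing_p = 0L, missing_maf = 0L, missing_pos = 0L,
              bad_maf = 0L, clamped_p0 = 0L, clamped_p1 = 0L)
  drop <- is.na(out$p)
  report["missing_p"] <- sum(drop)
  d <- !drop & is.na(out$maf); report["missing_maf"] <- sum(d); drop <- drop | d
  d <- !drop & is.na(out$pos); report["missing_pos"] <- sum(d); drop <- drop | d
  d <- !drop & (out$maf <= 0 | out$maf > 0.5)
  report["bad_maf"] <- sum(d); drop <- drop | d
  out <- out[!drop, , drop = FALSE]
  if (nrow(out) == 0L) stop("zero valid rows in ", path)

  p0 <- out$p == 0
  if (any(p0)) {
    warning(sum(p0), " p-value(s) of exactly 0 clamped to the smallest ",
            "positive double")
    out$p[p0] <- .Machine$double.xmin
    report["clamped_p0"] <- sum(p0)
  }
  p1 <- out$p > 1
  if (any(p1)) {
    out$p[p1] <- 1
    report["clamped_p1"] <- sum(p1)
  }
  if (any(out$p < 0)) stop("negative p-values in ", path)
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}

#' Write a summary-statistics table in the consortium layout
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`, `maf`,
#'   `beta`, `p`.
#' @param path Output path (tab-delimited, headers `legendrs`, `chr`,
#'   `pos`, `maf`, `beta`, `p_dgc`).
#' @export
write_sumstats <- function(snps, path) {
  stopifnot(is.data.frame(snps),
            all(c("snp_id", "chrom", "pos", "maf", "p") %in% names(snps)))
  out <- data.frame(legendrs = snps$snp_id, chr = snps$chrom,
                    pos = snps$pos, maf = snps$maf,
                    beta = if ("beta" %in% names(snps)) snps$beta
                    else NA_real_,
                    p_dgc = snps$p, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Write an annotation catalog as one id-list file per category
#'
#' @param catalog An `annotation_catalog`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, suitable for
#'   [load_catalog()].
#' @export
write_catalog <- function(catalog, dir) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(catalog$categories), function(nm) {
    path <- file.path(dir, paste0(nm, ".txt"))
    writeLines(catalog$categories[[nm]], path)
    path
  }, character(1L))
  paths
}

#' Write the per-SNP results spreadsheet
#'
#' Tab-delimited wide table: identifier block (`legendrs`, `chr`, `pos`,
#' `maf`, `beta`, `p_dgc`, `z_sq`), then per-annotation blocks in catalog
#' order with columns `LFDR.ME.<name>`, `LFDR.Big.<name>` (combined class),
#' `LFDR.Small.<name>` (separate class) and `Diff.<name>`
#' (`LFDR.Big - LFDR.ME`). Floats are printed at 6 significant digits.
#'
#' @param snps Panel data.frame (`snp_id`, `chrom`, `pos`, `maf`, `beta`,
#'   `p`).
#' @param results Named list of [estimate_class()] data.frames, as returned
#'   by [run_me_analysis()].
#' @param path Output path.
#' @param p_max Optional p-value cutoff: only rows with `p < p_max` are
#'   written (e.g. the deviated set); default `Inf` writes all.
#' @export
write_results <- function(snps, results, path, p_max = Inf) {
  stopifnot(is.data.frame(snps), nrow(snps) > 0L, length(results) > 0L,
            !is.null(names(results)))
  keep <- snps$p < p_max
  if (!any(keep)) stop("no rows below p_max = ", p_max)
  out <- data.frame(legendrs = snps$snp_id, chr = snps$chrom,
                    pos = snps$pos, maf = signif(snps$maf, 6),
                    beta = signif(snps$beta, 6),
                    p_dgc = signif(snps$p, 6),
                    z_sq = signif(pvalue_to_stat(snps$p), 6),
                    stringsAsFactors = FALSE)
  for (nm in names(results)) {
    est <- results[[nm]]
    ord <- match(snps$snp_id, est$snp_id)
    out[[paste0("LFDR.ME.", nm)]] <- signif(est$psi_me[ord], 6)
    out[[paste0("LFDR.Big.", nm)]] <- signif(est$psi_combined[ord], 6)
    out[[paste0("LFDR.Small.", nm)]] <- signif(est$psi_separate[ord], 6)
    out[[paste0("Diff.", nm)]] <- signif(est$diff[ord], 6)
  }
  data.table::fwrite(out[keep, , drop = FALSE], path, sep = "\t",
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a flat YAML config file
#'
#' @param path File path.
#' @return Named list of config values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
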