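# Annotation catalogs: named, possibly overlapping SNP-membership sets that
# define the separate reference classes over the panel.

#' Construct an annotation catalog
#'
#' @param categories Named list of character vectors of SNP ids. Categories
#'   may overlap; each must be non-empty.
#' @param panel_size Number of SNPs in the full panel.
#' @param report Optional reconciliation report (see [load_catalog()]).
#' @return An object of class `annotation_catalog`.
#' @export
annotation_catalog <- function(categories, panel_size, report = NULL) {
  stopifnot(is.list(categories))
  if (length(categories) > 0L)
    stopifnot(!is.null(names(categories)), all(nzchar(names(categories))))
  empty <- names(categories)[lengths(categories) == 0L]
  if (length(empty) > 0L)
    stop("empty category: ", paste(empty, collapse = ", "))
  structure(list(categories = lapply(categories, as.character),
                 panel_size = as.integer(panel_size),
                 report = report),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat(sprintf("annotation_catalog: %d categories over a panel of %d SNPs\n",
              length(x$categories), x$panel_size))
  for (nm in names(x$categories))
    cat(sprintf("  %-40s %d SNPs\n", nm, length(x$categories[[nm]])))
  invisible(x)
}

# Guess membership-file dialect: BED if >= 3 columns with numeric cols 2-3.
detect_annotation_dialect <- function(path) {
  first <- utils::head(readLines(path, n = 50L, warn = FALSE), 50L)
  first <- first[nzchar(first) & !startsWith(first, "#")]
  if (length(first) == 0L) return("ids")
  fields <- strsplit(first[1L], "[\t ]+")[[1L]]
  if (length(fields) >= 3L &&
      !is.na(suppressWarnings(as.numeric(fields[2L]))) &&
      !is.na(suppressWarnings(as.numeric(fields[3L]))))
    "bed" else "ids"
}

# Resolve a BED file (0-based half-open intervals) to panel SNP ids, with an
# optional symmetric extension window around every interval.
resolve_bed <- function(path, panel, extend_bp = 0) {
  bed <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end")[1:3],
                           colClasses = c("character", "numeric", "numeric"),
                           comment.char = "#", fill = FALSE)
  ids <- character(0)
  for (ch in unique(bed$chrom)) {
    pan <- panel[panel$chrom == ch, , drop = FALSE]
    if (nrow(pan) == 0L) next
    iv <- bed[bed$chrom == ch, , drop = FALSE]
    lo <- iv$start + 1 - extend_bp   # 1-based inclusive after extension
    hi <- iv$end + extend_bp
    hit <- rep(FALSE, nrow(pan))
    for (k in seq_len(nrow(iv)))
      hit <- hit | (pan$pos >= lo[k] & pan$pos <= hi[k])
    ids <- c(ids, pan$snp_id[hit])
  }
  unique(ids)
}

#' Load annotation categories from membership files
#'
#' Accepts two dialects per file, auto-detected: a plain list of SNP ids
#' (one per line) or BED intervals (0-based half-open; a SNP is a member if
#' its 1-based position falls inside any interval on the same chromosome,
#' after optional extension by `extend_bp` on both sides). Membership is
#' reconciled against the panel: ids not present are dropped and counted.
#'
#' @param paths Named character vector mapping category name to file path.
#' @param panel data.frame of panel SNPs with columns `snp_id`, `chrom`,
#'   `pos`.
#' @param extend_bp Window (bp) added around every BED interval (default 0).
#' @return An `annotation_catalog`; its `report` field is a data.frame with
#'   per-category `loaded`, `kept`, `dropped` counts (for id lists,
#'   `loaded` counts unique ids after deduplication).
#' @export
load_catalog <- function(paths, panel, extend_bp = 0) {
  stopifnot(length(paths) > 0L, !is.null(names(paths)),
            is.data.frame(panel), nrow(panel) > 0L,
            all(c("snp_id", "chrom", "pos") %in% names(panel)))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("annotation file not found: ", paste(missing, collapse = ", "))

  panel_ids <- panel$snp_id
  categories <- list()
  report <- data.frame(category = character(0), dialect = character(0),
                       loaded = integer(0), kept = integer(0),
                       dropped = integer(0), stringsAsFactors = FALSE)
  for (nm in names(paths)) {
    dialect <- detect_annotation_dialect(paths[[nm]])
    ids <- if (dialect == "bed") {
      resolve_bed(paths[[nm]], panel, extend_bp = extend_bp)
    } else {
      raw <- readLines(paths[[nm]], warn = FALSE)
      raw <- trimws(raw[nzchar(raw) & !startsWith(raw, "#")])
      if (anyDuplicated(raw)) {
        warning("category '", nm, "': ", sum(duplicated(raw)),
                " duplicate ids deduplicated")
        raw <- unique(raw)
      }
      raw
    }
    kept <- ids[ids %in% panel_ids]
    if (length(kept) == 0L)
      stop("category '", nm, "' is empty after reconciliation with the panel")
    categories[[nm]] <- kept
    report <- rbind(report, data.frame(
      category = nm, dialect = dialect, loaded = length(ids),
      kept = length(kept), dropped = length(ids) - length(kept),
      stringsAsFactors = FALSE))
  }
  annotation_catalog(categories, panel_size = nrow(panel), report = report)
}

#' Statistics of one category's member SNPs
#'
#' @param catalog An `annotation_catalog`.
#' @param category Category name.
#' @param stats Named numeric vector of statistics keyed by SNP id.
#' @return Named numeric vector restricted to the member SNPs, ordered by
#'   SNP id (order-stable).
#' @export
class_statistics <- function(catalog, category, stats) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  if (!category %in% names(catalog$categories))
    stop("unknown category: ", category)
  ids <- sort(intersect(catalog$categories[[category]], names(stats)))
  if (length(ids) == 0L)
    stop("category '", category, "' has no statistics in the supplied set")
  stats[ids]
}
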