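#' @title Homozygosity mapping
#' @description Locates a recessive disease locus from case/control
#'   genotypes: exact detection of the maximal interval homozygous and
#'   identical by state across all cases, and a simplified haplotype-window
#'   association scan.
#' @name autozygosity
NULL

#' Maximal shared-homozygosity (IBS) intervals across cases
#'
#' A marker is *concordant* iff every non-missing case genotype is
#' homozygous for the same allele (all 0 or all 2) and at most
#' `max_missing_per_marker` cases are missing.  Returns, per chromosome, the
#' maximal runs of consecutive concordant markers of at least `min_markers`
#' markers, with boundaries at the outermost concordant markers.
#'
#' @param gm a [genotype_matrix()].
#' @param case_ids sample ids of the affected individuals.
#' @param max_missing_per_marker missing-call tolerance per marker.
#' @param min_markers minimum run length reported.
#' @return data.frame(chrom, start_bp, end_bp, n_markers), genome-ordered.
#' @export
shared_homozygosity_segments <- function(gm, case_ids,
                                         max_missing_per_marker = 0L,
                                         min_markers = 10L) {
  stopifnot(inherits(gm, "genotype_matrix"), min_markers >= 1L)
  miss <- setdiff(case_ids, gm$samples)
  if (length(miss)) stop("unknown case id(s): ", paste(miss, collapse = ", "))
  g <- gm$geno[match(case_ids, gm$samples), , drop = FALSE]
  n_na <- colSums(is.na(g))
  all0 <- colSums(g == 0L, na.rm = TRUE) + n_na == length(case_ids)
  all2 <- colSums(g == 2L, na.rm = TRUE) + n_na == length(case_ids)
  concordant <- (all0 | all2) &
    n_na <= max_missing_per_marker &
    n_na < length(case_ids)          # a fully missing marker decides nothing
  out <- list()
  for (cn in unique(gm$markers$chrom)) {
    sel <- which(gm$markers$chrom == cn)
    r <- rle(concordant[sel])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_markers
    if (!any(keep)) next
    out[[cn]] <- data.frame(
      chrom = cn,
      start_bp = gm$markers$pos[sel[starts[keep]]],
      end_bp = gm$markers$pos[sel[ends[keep]]],
      n_markers = r$lengths[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_markers = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Interval length in megabases
#'
#' `(end_bp - start_bp) / 1e6`, rounded to two decimals — the convention
#' under which chr25:632,647-1,781,139 is a 1.15-Mb interval.
#'
#' @param interval list or one-row data.frame with `start_bp`, `end_bp`.
#' @return Numeric length in Mb.
#' @export
interval_length_mb <- function(interval) {
  if (interval$end_bp < interval$start_bp) stop("end_bp < start_bp")
  round((interval$end_bp - interval$start_bp) / 1e6, 2L)
}

#' Case/control haplotype-window association scan
#'
#' For each window of `window_size` consecutive markers (stepping by `step`),
#' the two phased haplotypes of every individual are reduced to allele
#' strings; the Pearson chi-square statistic of the (distinct haplotype
#' string) x (phenotype) contingency table over chromosomes is reported with
#' df = number of distinct haplotype classes - 1.  Haplotypes observed fewer
#' than `min_count` times are pooled into a single rare class; the fairly
#' aggressive default (8 chromosomes) makes this a common-haplotype scan,
#' which keeps the degrees of freedom low and concentrates a founder-derived
#' signal instead of diffusing it over dozens of singleton haplotype
#' classes.  This is a deliberately simple substitute for a mixed-model
#' haplotype association scan: phased input and no stratification
#' correction.
#'
#' @param haps a haplotype_set (phased by construction).
#' @param labels named character vector over \{"affected", "unaffected"\};
#'   names select the scanned individuals.
#' @param window_size markers per window.
#' @param step step between window starts, markers.
#' @param min_count pooling threshold for rare haplotypes.
#' @return data.frame of class `scan_result`: window id, chrom, start_bp,
#'   end_bp, mid_bp, statistic, df, p, neg_log10_p; genome-ordered.
#' @export
haplotype_window_scan <- function(haps, labels, window_size = 10L,
                                  step = 5L, min_count = 8L) {
  stopifnot(window_size >= 1L, step >= 1L)
  ids <- names(labels)
  if (is.null(ids) || !all(ids %in% haps$ids))
    stop("labels must be named by individual ids present in the haplotype set")
  if (!all(labels %in% c("affected", "unaffected")))
    stop("labels must be 'affected' or 'unaffected'")
  if (length(unique(labels)) < 2L)
    stop("both label classes must be non-empty")
  idx <- match(ids, haps$ids)
  pheno2 <- rep(labels, 2L)            # one entry per chromosome copy
  rows <- list(); wid <- 0L
  for (cn in names(haps$chroms)) {
    ch <- haps$chroms[[cn]]
    keep <- which(ch$is_array)
    h <- rbind(ch$h1[idx, keep, drop = FALSE], ch$h2[idx, keep, drop = FALSE])
    pos <- ch$pos[keep]
    m <- length(pos)
    if (m < window_size) next
    for (s in seq(1L, m - window_size + 1L, by = step)) {
      cols <- s:(s + window_size - 1L)
      hs <- do.call(paste0, as.data.frame(h[, cols, drop = FALSE]))
      res <- haplotype_table_chisq(hs, pheno2, min_count)
      wid <- wid + 1L
      rows[[wid]] <- data.frame(
        window = wid, chrom = cn,
        start_bp = pos[s], end_bp = pos[s + window_size - 1L],
        mid_bp = (pos[s] + pos[s + window_size - 1L]) / 2,
        statistic = res$stat, df = res$df, p = res$p,
        neg_log10_p = -log10(res$p),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scan_result", class(out))
  out
}

## Pearson chi-square of haplotype-class x phenotype counts with rare-class
## pooling; a window with a single class carries no information (stat 0, p 1).
haplotype_table_chisq <- function(hap_strings, pheno, min_count) {
  counts <- table(hap_strings)
  rare <- names(counts)[counts < min_count]
  if (length(rare) > 0L)
    hap_strings[hap_strings %in% rare] <- ".rare"
  k <- length(unique(hap_strings))
  if (k < 2L) return(list(stat = 0, df = 0L, p = 1))
  tab <- table(hap_strings, pheno)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- k - 1L
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Serialize a scan as a Manhattan table
#'
#' One row per window midpoint, genome order preserved.
#'
#' @param scan a `scan_result`.
#' @param path optional TSV path; when given the table is also written.
#' @return data.frame(chrom, position, neg_log10_p).
#' @export
manhattan_table <- function(scan, path = NULL) {
  if (!nrow(scan)) stop("empty scan")
  tab <- data.frame(chrom = scan$chrom, position = scan$mid_bp,
                    neg_log10_p = scan$neg_log10_p)
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tab
}
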