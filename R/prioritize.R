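#' @title Private-variant filtering cascades
#' @description Two filtering strategies that single out a private causal
#'   variant from a multi-sample callset.  Cascade A: discard variants seen
#'   in controls or in a known-variants catalogue, keep those hom-alt in all
#'   cases, then narrow by region (transcribed, ORF) down to
#'   amino-acid-changing variants with codon-aware MNV annotation.
#'   Cascade B: keep only variants hom-alt in all cases, het in all carriers
#'   and absent from all non-carriers, then break the survivors down by
#'   region and coding consequence.
#' @name prioritize
NULL

#' Remove variants found in controls or in the known catalogue
#'
#' A variant is removed iff any control genotype carries the alt allele
#' (het or hom-alt) or its (chrom, pos, ref, alt) key is in the catalogue.
#' Input order is preserved.
#'
#' @param gm a [genotype_matrix()] callset.
#' @param control_ids sample ids of the control cohort.
#' @param catalogue data.frame with chrom/pos/ref/alt (may be empty).
#' @return list(retained = genotype_matrix, removed = count,
#'   removed_keys = character).
#' @export
filter_known_or_in_controls <- function(gm, control_ids, catalogue) {
  miss <- setdiff(control_ids, gm$samples)
  if (length(miss)) stop("unknown control id(s): ", paste(miss, collapse = ", "))
  ctl <- gm$geno[match(control_ids, gm$samples), , drop = FALSE]
  in_controls <- colSums(ctl >= 1L, na.rm = TRUE) > 0L
  keys <- variant_keys(gm)
  cat_keys <- if (nrow(catalogue))
    paste(catalogue$chrom, catalogue$pos, catalogue$ref, catalogue$alt,
          sep = ":") else character()
  known <- keys %in% cat_keys
  drop <- in_controls | known
  list(retained = subset_genotypes(gm, markers = which(!drop)),
       removed = sum(drop), removed_keys = keys[drop])
}

## hom-alt in every case; a missing case call cannot certify "all"
hom_in_all_cases <- function(gm, case_ids) {
  g <- gm$geno[match(case_ids, gm$samples), , drop = FALSE]
  colSums(g == 2L, na.rm = TRUE) == length(case_ids)
}

#' Cascade A: private-variant filtering against controls and catalogue
#'
#' Pipeline: [filter_known_or_in_controls()] -> keep variants hom-alt in all
#' cases -> transcribed (exonic) -> ORF (CDS) -> amino-acid-changing, with
#' the last step decided by joint per-codon (MNV) annotation.  "Transcribed"
#' counts exonic positions only (UTR or CDS), not introns.
#'
#' @param gm callset [genotype_matrix()].
#' @param case_ids,control_ids disjoint cohorts.
#' @param catalogue known-variants data.frame (chrom/pos/ref/alt).
#' @param gene a `toy_gene` model.
#' @return list of class `cascade_a_report`: `counts` (total,
#'   removed_known_or_in_controls, remaining, hom_all_cases, in_transcribed,
#'   in_orf, aa_changing), `percent_removed_step1` (nearest integer),
#'   `retained` (marker tables per step), `consequences` (one
#'   `consequence_record` per amino-acid-changing codon group).
#' @export
cascade_a <- function(gm, case_ids, control_ids, catalogue, gene) {
  if (length(intersect(case_ids, control_ids)))
    stop("case and control cohorts overlap")
  total <- nrow(gm$markers)
  step1 <- filter_known_or_in_controls(gm, control_ids, catalogue)
  g1 <- step1$retained
  keep_hom <- if (nrow(g1$markers)) hom_in_all_cases(g1, case_ids) else logical()
  g2 <- subset_genotypes(g1, markers = which(keep_hom))
  region <- classify_region(g2$markers$pos, gene, g2$markers$chrom)
  g3 <- subset_genotypes(g2, markers = which(region %in% c("CDS", "exonic-noncoding")))
  region3 <- classify_region(g3$markers$pos, gene, g3$markers$chrom)
  g4 <- subset_genotypes(g3, markers = which(region3 == "CDS"))
  cons <- annotate_cds_markers(g4$markers, gene)
  changing <- Filter(function(x) x$record$class != "synonymous", cons)
  aa_variants <- unlist(lapply(changing, function(x) x$keys))
  counts <- c(total = total,
              removed_known_or_in_controls = step1$removed,
              remaining = nrow(g1$markers),
              hom_all_cases = nrow(g2$markers),
              in_transcribed = nrow(g3$markers),
              in_orf = nrow(g4$markers),
              aa_changing = length(aa_variants))
  structure(list(
    counts = counts,
    percent_removed_step1 =
      if (total) as.integer(round(100 * step1$removed / total)) else 0L,
    retained = list(after_control_catalogue = g1$markers,
                    hom_all_cases = g2$markers,
                    transcribed = g3$markers, orf = g4$markers,
                    aa_changing = aa_variants),
    consequences = lapply(cons, `[[`, "record")),
    class = "cascade_a_report")
}

## annotate the CDS markers of a cascade step; returns one entry per codon
## group: list(record = consequence_record, keys = member variant keys)
annotate_cds_markers <- function(markers, gene) {
  if (!nrow(markers)) return(list())
  cdsv <- variants_to_cds(gene, markers$chrom, markers$pos,
                          markers$ref, markers$alt)
  if (!nrow(cdsv)) return(list())
  key_by_cds <- paste(markers$chrom, markers$pos, markers$ref, markers$alt,
                      sep = ":")[match(cds_to_genomic(gene, cdsv$cds_pos),
                                       markers$pos)]
  groups <- group_codon_mnv(cdsv, nchar(gene$cds_seq))
  lapply(groups, function(gr) {
    list(record = annotate_codon_group(gr, gene$cds_seq),
         keys = key_by_cds[match(gr$members$cds_pos, cdsv$cds_pos)])
  })
}

#' Cascade B: case/carrier/control segregation filter
#'
#' A variant survives iff it is hom-alt in *all* cases, het in *all*
#' carriers, and the alt allele is absent from *all* non-carriers.  Missing
#' genotypes: over cases and carriers a missing call disqualifies (it cannot
#' certify an "all" criterion); over non-carriers a missing call counts as
#' absent, with a warning.  Survivors are broken down as intergenic /
#' intronic / coding (coding = CDS; UTR counts with intergenic), and coding
#' survivors are split synonymous vs non-synonymous by joint MNV annotation.
#'
#' @param gm callset [genotype_matrix()].
#' @param case_ids,carrier_ids,noncarrier_ids pairwise-disjoint, non-empty
#'   cohorts.
#' @param gene a `toy_gene` model.
#' @param missing_noncarrier_absent treat a missing non-carrier call as
#'   absence of the alt allele (default TRUE, with a warning when it
#'   happens).
#' @return list of class `cascade_b_report`: `survivors` (marker table),
#'   `breakdown` (intergenic/intronic/coding counts), `coding_split`
#'   (synonymous/non_synonymous), `consequences`.
#' @export
cascade_b <- function(gm, case_ids, carrier_ids, noncarrier_ids, gene,
                      missing_noncarrier_absent = TRUE) {
  cohorts <- list(case_ids, carrier_ids, noncarrier_ids)
  if (any(!lengths(cohorts))) stop("all three cohorts must be non-empty")
  for (i in 1:2) for (j in (i + 1L):3L)
    if (length(intersect(cohorts[[i]], cohorts[[j]])))
      stop("cohorts overlap")
  miss <- setdiff(unlist(cohorts), gm$samples)
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  gca <- gm$geno[match(case_ids, gm$samples), , drop = FALSE]
  gcr <- gm$geno[match(carrier_ids, gm$samples), , drop = FALSE]
  gnc <- gm$geno[match(noncarrier_ids, gm$samples), , drop = FALSE]
  ok_cases <- colSums(gca == 2L, na.rm = TRUE) == length(case_ids)
  ok_carriers <- colSums(gcr == 1L, na.rm = TRUE) == length(carrier_ids)
  if (missing_noncarrier_absent) {
    if (anyNA(gnc))
      warning("missing non-carrier genotype(s) treated as absence of the alt allele")
    ok_nc <- colSums(gnc >= 1L, na.rm = TRUE) == 0L
  } else {
    ok_nc <- colSums(gnc == 0L, na.rm = TRUE) == length(noncarrier_ids)
  }
  surv <- which(ok_cases & ok_carriers & ok_nc)
  gs <- subset_genotypes(gm, markers = surv)
  region <- classify_region(gs$markers$pos, gene, gs$markers$chrom)
  breakdown <- c(
    intergenic = sum(region %in% c("intergenic", "exonic-noncoding")),
    intronic = sum(region == "intronic"),
    coding = sum(region == "CDS"))
  cons <- annotate_cds_markers(gs$markers[region == "CDS", , drop = FALSE], gene)
  n_nonsyn <- sum(unlist(lapply(cons, function(x)
    if (x$record$class == "synonymous") 0L else length(x$keys))))
  coding_split <- c(synonymous = unname(breakdown["coding"]) - n_nonsyn,
                    non_synonymous = n_nonsyn)
  structure(list(survivors = gs$markers, breakdown = breakdown,
                 coding_split = coding_split,
                 consequences = lapply(cons, `[[`, "record")),
            class = "cascade_b_report")
}

#' @export
print.cascade_a_report <- function(x, ...) {
  cat("Cascade A (control/catalogue private-variant filter)\n")
  cat(sprintf("  note: the case criterion (hom-alt in all cases) is applied explicitly\n"))
  for (nm in names(x$counts)) cat(sprintf("  %-30s %d\n", nm, x$counts[[nm]]))
  cat(sprintf("  %% removed at step 1: %d%%\n", x$percent_removed_step1))
  invisible(x)
}

#' @export
print.cascade_b_report <- function(x, ...) {
  cat("Cascade B (case hom / carrier het / control absent)\n")
  cat(sprintf("  survivors: %d (intergenic %d, intronic %d, coding %d; coding: %d syn, %d non-syn)\n",
              nrow(x$survivors), x$breakdown["intergenic"],
              x$breakdown["intronic"], x$breakdown["coding"],
              x$coding_split["synonymous"], x$coding_split["non_synonymous"]))
  invisible(x)
}
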