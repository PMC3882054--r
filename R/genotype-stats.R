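#' @title Population-genetic checks on genotyping results
#' @name genotype-stats
NULL

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Default is the Pearson chi-square over the three genotype classes with
#' the allele frequency estimated from the data, df = 1, no continuity
#' correction: with counts (5845 hom-ref, 644 het, 0 hom-alt) this gives
#' p = 2.6e-5, i.e. a significant deficit of mutant homozygotes among
#' controls — the signature of a recessive lethal.  A Yates-corrected
#' variant and an exact test (full enumeration of heterozygote counts
#' conditional on allele counts) are available as options.
#'
#' @param n_homref,n_het,n_homalt genotype class counts.
#' @param method "pearson" (default), "yates" or "exact".
#' @return list(statistic, df, p, q_hat, expected); `statistic`/`df` are NA
#'   for the exact test.  If only one allele is observed, p = 1 by
#'   convention.
#' @export
hwe_test <- function(n_homref, n_het, n_homalt,
                     method = c("pearson", "yates", "exact")) {
  method <- match.arg(method)
  counts <- c(n_homref, n_het, n_homalt)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  N <- sum(counts)
  if (N < 1) stop("total count must be >= 1")
  n_alt <- n_het + 2 * n_homalt
  q <- n_alt / (2 * N)
  expected <- N * c((1 - q)^2, 2 * q * (1 - q), q^2)
  if (q == 0 || q == 1)
    return(list(statistic = 0, df = 1L, p = 1, q_hat = q, expected = expected))
  if (method == "exact") {
    return(list(statistic = NA_real_, df = NA_integer_,
                p = hwe_exact_p(counts), q_hat = q, expected = expected))
  }
  dev <- abs(counts - expected)
  if (method == "yates") dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       q_hat = q, expected = expected)
}

## Exact HWE p-value: enumerate all heterozygote counts compatible with the
## observed allele counts and sum the probabilities of tables no more likely
## than the observed one (two-sided, by probability ordering).
hwe_exact_p <- function(counts) {
  N <- sum(counts); n_alt <- counts[2] + 2 * counts[3]
  hets <- seq(n_alt %% 2, min(n_alt, 2 * N - n_alt), by = 2)
  logp <- vapply(hets, function(h) {
    na <- (n_alt - h) / 2; nr <- N - na - h
    lchoose(N, na) + lchoose(N - na, h) + h * log(2) -
      lchoose(2 * N, n_alt)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[match(counts[2], hets)]
  sum(p[p <= obs + 1e-12])
}

#' Minor (alt) allele frequency as a percentage
#'
#' `100 * (n_het + 2 * n_homalt) / (2N)`.  Note the distinction from the
#' carrier frequency: 644 carriers among 6489 animals is a 9.9% carrier
#' frequency but a 5.0% allele frequency.
#'
#' @param n_homref,n_het,n_homalt genotype class counts.
#' @return list(percent, rendered) where `rendered` is the nearest-integer
#'   string (e.g. "5%").
#' @export
allele_frequency_percent <- function(n_homref, n_het, n_homalt) {
  N <- n_homref + n_het + n_homalt
  if (N < 1) stop("total count must be >= 1")
  pct <- 100 * (n_het + 2 * n_homalt) / (2 * N)
  list(percent = pct, rendered = paste0(round(pct), "%"))
}

#' Verify recessive segregation of a genotyped variant in a pedigree
#'
#' Flags every affected individual not hom-alt, every genotyped parent of an
#' affected that is not het, and every unaffected/control individual that is
#' hom-alt.  Samples marked external (outside the pedigree) are checked only
#' for presence of the alt allele.
#'
#' @param pedigree data.frame with `id`, `sire`, `dam`, `phenotype`.
#' @param genotypes named integer vector (0/1/2, NA missing) over sample ids.
#' @param external ids in `genotypes` that are outside the pedigree (an
#'   other-breed cohort); any alt allele there is a violation.
#' @return list of class `segregation_report`: `violations` (list of id
#'   vectors by type: affected_not_homozygous, parent_of_affected_not_carrier,
#'   unaffected_homozygote, external_with_alt), `pass`.
#' @export
check_recessive_segregation <- function(pedigree, genotypes,
                                        external = character()) {
  ids <- names(genotypes)
  unknown <- setdiff(ids, c(pedigree$id, external))
  if (length(unknown))
    stop("genotyped id(s) neither in pedigree nor marked external: ",
         paste(unknown, collapse = ", "))
  ped_ids <- setdiff(ids, external)
  g <- genotypes[ped_ids]
  pheno <- pedigree$phenotype[match(ped_ids, pedigree$id)]
  affected <- ped_ids[pheno == "affected"]
  v1 <- affected[!is.na(genotypes[affected]) & genotypes[affected] != 2L]
  par_aff <- unique(stats::na.omit(c(
    pedigree$sire[pedigree$id %in% affected],
    pedigree$dam[pedigree$id %in% affected])))
  par_typed <- intersect(par_aff, ped_ids)
  v2 <- par_typed[!is.na(genotypes[par_typed]) & genotypes[par_typed] != 1L]
  unaff <- ped_ids[pheno != "affected"]
  v3 <- unaff[!is.na(genotypes[unaff]) & genotypes[unaff] == 2L]
  ext_typed <- intersect(external, ids)
  v4 <- ext_typed[!is.na(genotypes[ext_typed]) & genotypes[ext_typed] >= 1L]
  violations <- list(affected_not_homozygous = v1,
                     parent_of_affected_not_carrier = v2,
                     unaffected_homozygote = v3,
                     external_with_alt = v4)
  structure(list(violations = violations,
                 pass = all(lengths(violations) == 0L)),
            class = "segregation_report")
}

#' @export
print.segregation_report <- function(x, ...) {
  cat("Recessive segregation check:", if (x$pass) "PASS" else "FAIL", "\n")
  for (nm in names(x$violations))
    if (length(x$violations[[nm]]))
      cat(sprintf("  %s: %s\n", nm,
                  paste(x$violations[[nm]], collapse = ", ")))
  invisible(x)
}

#' Carrier and allele frequencies by group
#'
#' @param genotypes integer vector (0/1/2, NA missing).
#' @param groups parallel character vector of group labels.
#' @return data.frame with one row per group plus a totals row: n, carriers,
#'   homozygotes, carrier_pct, allele_pct.
#' @export
carrier_frequency_by_group <- function(genotypes, groups) {
  if (length(genotypes) != length(groups))
    stop("genotypes and groups must be parallel")
  if (any(is.na(groups) | groups == ""))
    stop("empty group label")
  one <- function(g) {
    g <- g[!is.na(g)]
    n <- length(g)
    if (!n) stop("group with no called genotypes")
    data.frame(n = n, carriers = sum(g == 1L), homozygotes = sum(g == 2L),
               carrier_pct = 100 * sum(g == 1L) / n,
               allele_pct = 100 * sum(g) / (2 * n))
  }
  per <- do.call(rbind, lapply(split(genotypes, groups), one))
  out <- rbind(per, total = one(genotypes))
  cbind(group = rownames(out), out, row.names = NULL)
}
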