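#' @title Array genotypes and WGS-like callsets from simulated haplotypes
#' @name sim-genotypes
NULL

#' Emit SNP-array genotypes from simulated haplotypes
#'
#' The genotype at each array marker is the sum of the two haplotype alleles,
#' perturbed to a uniformly chosen *different* genotype with probability
#' `error_rate` (a simple array-call error model).  Marker ref/alt alleles
#' are written as A/G throughout.
#'
#' @param haps a haplotype_set.
#' @param error_rate per-call perturbation probability.
#' @param seed integer seed.
#' @param samples sample ids to emit (default: all individuals).
#' @return A [genotype_matrix()] over the array markers.
#' @export
emit_array_genotypes <- function(haps, error_rate = 0, seed = 1L,
                                 samples = NULL) {
  set.seed(seed)
  if (is.null(samples)) samples <- haps$ids
  miss <- setdiff(samples, haps$ids)
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  idx <- match(samples, haps$ids)
  blocks <- list(); mk <- list()
  for (cn in names(haps$chroms)) {
    ch <- haps$chroms[[cn]]
    keep <- ch$is_array
    g <- ch$h1[idx, keep, drop = FALSE] + ch$h2[idx, keep, drop = FALSE]
    if (error_rate > 0) {
      flip <- which(matrix(stats::runif(length(g)) < error_rate, nrow(g)))
      if (length(flip)) {
        shift <- sample(1:2, length(flip), replace = TRUE)
        g[flip] <- (g[flip] + shift) %% 3L
      }
    }
    blocks[[cn]] <- g
    mk[[cn]] <- data.frame(chrom = cn, pos = ch$pos[keep],
                           ref = "A", alt = "G", stringsAsFactors = FALSE)
  }
  genotype_matrix(samples, do.call(rbind, mk), do.call(cbind, blocks))
}

## CDS positions (third codon bases) whose codon tolerates a synonymous
## single-base change; returns data.frame(cds_pos, ref, alt), excluding the
## codon window around the causal cluster.
synonymous_sites <- function(cds_seq, exclude_codons = 745:755) {
  n_codon <- nchar(cds_seq) %/% 3L
  out <- list()
  for (k in setdiff(seq_len(n_codon), exclude_codons)) {
    codon <- substring(cds_seq, 3L * k - 2L, 3L * k)
    aa <- CODON_TABLE_1[codon]
    for (alt in setdiff(c("A", "C", "G", "T"), substring(codon, 3L, 3L))) {
      mut <- codon
      substr(mut, 3L, 3L) <- alt
      if (identical(unname(CODON_TABLE_1[mut]), unname(aa))) {
        out[[length(out) + 1L]] <- data.frame(
          cds_pos = 3L * k, ref = substring(codon, 3L, 3L), alt = alt,
          stringsAsFactors = FALSE)
        break  # one synonymous alt per codon is enough
      }
    }
  }
  do.call(rbind, out)
}

#' Emit a WGS-like variant callset with a planted causal MNV cluster
#'
#' Generates per-sample genotypes over a sequenced region around the toy
#' gene for three cohorts drawn from the population by true carrier state:
#' affected cases, obligate carriers and non-carrier controls.  The callset
#' contains
#' \itemize{
#'   \item the three causal cluster substitutions (hom-alt in cases, het in
#'     carriers, absent in controls, by carrier state);
#'   \item `n_linked_*` variants in perfect co-segregation with the disease
#'     haplotype, placed intergenic / intronic / coding-synonymous by
#'     construction (the private linked neighbourhood of an IBD segment);
#'   \item Poisson(`density` x region length) background variants, each
#'     either population-shared (present in at least one control) with
#'     probability `p_in_controls`, or sporadic (het in one random sample).
#' }
#' A known-variants catalogue is drawn from the background variants only
#' (never the cluster or the linked set) at `catalogue_fraction`.
#'
#' @param pop a `sim_population` from [build_population()].
#' @param config a [sim_config()] (defaults to the population's).
#' @param seed integer seed.
#' @return list of class `wgs_callset`: `callset` ([genotype_matrix()]),
#'   `catalogue` (data.frame chrom/pos/ref/alt), `truth` (per-variant
#'   bookkeeping: class, in_controls, in_catalogue, region, hom_all_cases),
#'   `cohorts` (cases/carriers/noncarriers), `region`, `gene`, `cluster`.
#' @export
emit_wgs_callset <- function(pop, config = pop$config, seed = 1L) {
  set.seed(seed)
  gene <- pop$gene; cluster <- pop$cluster
  if (!all(classify_region(cluster$genomic_positions, gene) == "CDS"))
    stop("causal cluster does not lie in a coding exon")
  ped <- pop$pedigree
  pick <- function(state, n, what) {
    ids <- ped$id[ped$carrier_state == state]
    if (length(ids) < n)
      stop("not enough ", what, " individuals (need ", n, ", have ",
           length(ids), ")")
    if (state == "homozygous") ids[seq_len(n)] else sample(ids, n)
  }
  cases <- pick("homozygous", config$n_wgs_cases, "affected")
  carriers <- pick("carrier", config$n_wgs_carriers, "carrier")
  noncarriers <- pick("noncarrier", config$n_wgs_noncarriers, "non-carrier")
  samples <- c(cases, carriers, noncarriers)
  state <- c(rep(2L, length(cases)), rep(1L, length(carriers)),
             rep(0L, length(noncarriers)))

  region <- c(max(1L, gene$tx_start - config$region_flank),
              gene$tx_end + config$region_flank)
  region_len <- region[2] - region[1] + 1L

  ## ---- linked variants, placed by region class by construction ----
  sample_spans <- function(spans, n) {
    len <- spans$end - spans$start + 1L
    repeat {
      i <- sample.int(nrow(spans), n, replace = TRUE, prob = len)
      p <- spans$start[i] + vapply(len[i], function(l) sample.int(l, 1L), 1L) - 1L
      if (!anyDuplicated(p)) return(p)
    }
  }
  intergenic_spans <- data.frame(
    start = c(region[1], gene$tx_end + 1L),
    end = c(gene$tx_start - 1L, region[2]))
  ex <- gene$exons[order(gene$exons$start), ]
  intron_spans <- data.frame(start = utils::head(ex$end, -1L) + 1L,
                             end = ex$start[-1L] - 1L)
  li_pos <- sample_spans(intergenic_spans, config$n_linked_intergenic)
  lin_pos <- sample_spans(intron_spans, config$n_linked_intronic)
  syn <- synonymous_sites(gene$cds_seq)
  syn <- syn[sample(nrow(syn), config$n_linked_synonymous), , drop = FALSE]
  flip <- gene$strand == "-"
  syn_ref <- if (flip) comp_base(syn$ref) else syn$ref
  syn_alt <- if (flip) comp_base(syn$alt) else syn$alt
  syn_pos <- cds_to_genomic(gene, syn$cds_pos)
  linked <- data.frame(
    pos = c(li_pos, lin_pos, syn_pos),
    ref = c(random_bases(length(li_pos) + length(lin_pos)), syn_ref),
    alt = NA_character_,
    region = c(rep("intergenic", length(li_pos)),
               rep("intronic", length(lin_pos)),
               rep("CDS", length(syn_pos))),
    stringsAsFactors = FALSE)
  nb <- length(li_pos) + length(lin_pos)
  linked$alt[seq_len(nb)] <- random_bases(nb, avoid = linked$ref[seq_len(nb)])
  linked$alt[nb + seq_along(syn_pos)] <- syn_alt

  ## ---- background variants ----
  n_bg <- stats::rpois(1L, config$background_variant_density * region_len / 1000)
  taken <- c(cluster$genomic_positions, linked$pos)
  bg_pos <- region[1] - 1L + sample.int(region_len, n_bg + length(taken) + 50L)
  bg_pos <- sort(setdiff(bg_pos, taken)[seq_len(n_bg)])
  bg_cds <- genomic_to_cds(gene, bg_pos)
  bg_ref <- random_bases(n_bg)
  in_cds <- !is.na(bg_cds)
  if (any(in_cds)) {  # respect the genome where a sequence exists
    cds_base <- substring(gene$cds_seq, bg_cds[in_cds], bg_cds[in_cds])
    bg_ref[in_cds] <- if (flip) comp_base(cds_base) else cds_base
  }
  bg_alt <- random_bases(n_bg, avoid = bg_ref)
  bg_shared <- stats::runif(n_bg) < config$p_in_controls

  geno_bg <- matrix(0L, length(samples), n_bg)
  nc_idx <- which(state == 0L)
  for (j in seq_len(n_bg)) {
    if (bg_shared[j]) {
      u <- stats::runif(1, 0.05, 0.5)
      geno_bg[, j] <- stats::rbinom(length(samples), 2L, u)
      if (all(geno_bg[nc_idx, j] == 0L))
        geno_bg[sample(nc_idx, 1L), j] <- 1L
    } else {
      geno_bg[sample(length(samples), 1L), j] <- 1L
    }
  }
  ## a sporadic variant hosted by a control is "in controls" too
  bg_in_controls <- bg_shared | colSums(geno_bg[nc_idx, , drop = FALSE]) > 0L
  bg_catalogued <- stats::runif(n_bg) < config$catalogue_fraction

  ## ---- assemble ----
  seg_geno <- matrix(rep(state, length(linked$pos) + 3L),
                     length(samples))  # carrier-state genotypes
  variants <- data.frame(
    chrom = gene$chrom,
    pos = c(cluster$genomic_positions, linked$pos, bg_pos),
    ref = c(cluster$ref_genomic, linked$ref, bg_ref),
    alt = c(cluster$alt_genomic, linked$alt, bg_alt),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    chrom = gene$chrom,
    pos = variants$pos, ref = variants$ref, alt = variants$alt,
    class = c(rep("cluster", 3L), rep("linked", nrow(linked)),
              rep("background", n_bg)),
    region = c(rep("CDS", 3L), linked$region,
               classify_region(bg_pos, gene)),
    in_controls = c(rep(FALSE, 3L + nrow(linked)), bg_in_controls),
    in_catalogue = c(rep(FALSE, 3L + nrow(linked)), bg_catalogued),
    hom_all_cases = c(rep(TRUE, 3L + nrow(linked)),
                      colSums(geno_bg[state == 2L, , drop = FALSE] == 2L) ==
                        sum(state == 2L)),
    stringsAsFactors = FALSE)
  geno <- cbind(seg_geno, geno_bg)
  ord <- order(variants$pos)
  callset <- genotype_matrix(samples, variants[ord, ], geno[, ord])
  cat_rows <- truth$in_catalogue
  catalogue <- unique(truth[cat_rows, c("chrom", "pos", "ref", "alt")])
  rownames(catalogue) <- NULL
  truth <- truth[ord, ]; rownames(truth) <- NULL
  structure(list(callset = callset, catalogue = catalogue, truth = truth,
                 cohorts = list(cases = cases, carriers = carriers,
                                noncarriers = noncarriers),
                 region = region, gene = gene, cluster = cluster),
            class = "wgs_callset")
}

random_bases <- function(n, avoid = NULL) {
  b <- c("A", "C", "G", "T")
  if (is.null(avoid)) return(sample(b, n, replace = TRUE))
  vapply(avoid, function(a) sample(setdiff(b, a), 1L), "")
}
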