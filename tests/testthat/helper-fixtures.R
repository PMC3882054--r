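## Shared fixtures: small configs and populations built once per test run.

fast_config <- function(...) {
  args <- list(n_founders = 12, n_generations = 2, matings_per_generation = 12,
               target_n_cases = 1, max_attempts = 50,
               chromosome_lengths = c(chr1 = 30e6), marker_spacing = 3e5,
               n_wgs_cases = 1, n_wgs_carriers = 2, n_wgs_noncarriers = 2,
               n_array_controls = 10, background_variant_density = 0.2)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

## one default-scale population reused by several test files
default_pop <- local({
  pop <- NULL
  function() {
    if (is.null(pop)) pop <<- build_population(sim_config(), seed = 42L)
    pop
  }
})

## a tiny two-founder pedigree (sire x dam -> n_off offspring)
trio_pedigree <- function(n_off = 1L) {
  data.frame(
    id = c("S", "D", sprintf("C%03d", seq_len(n_off))),
    sire = c(NA, NA, rep("S", n_off)),
    dam = c(NA, NA, rep("D", n_off)),
    sex = c("M", "F", rep("M", n_off)),
    generation = c(0L, 0L, rep(1L, n_off)),
    stringsAsFactors = FALSE)
}

## founder haplotypes over explicit marker positions, fixed alleles
manual_founder_haps <- function(ids, pos, cm = pos / 1e6, alleles = NULL) {
  n <- length(ids); m <- length(pos)
  if (is.null(alleles)) alleles <- matrix(0L, 2L * n, m)
  h1 <- alleles[seq(1, 2 * n, 2), , drop = FALSE]
  h2 <- alleles[seq(2, 2 * n, 2), , drop = FALSE]
  o1 <- matrix(rep(2L * (seq_len(n) - 1L) + 1L, m), n, m)
  o2 <- matrix(rep(2L * (seq_len(n) - 1L) + 2L, m), n, m)
  rownames(h1) <- rownames(h2) <- rownames(o1) <- rownames(o2) <- ids
  storage.mode(h1) <- "integer"; storage.mode(h2) <- "integer"
  structure(list(ids = ids,
                 chroms = list(chr1 = list(pos = pos, cm = cm,
                                           is_array = rep(TRUE, m),
                                           h1 = h1, h2 = h2,
                                           o1 = o1, o2 = o2))),
            class = "haplotype_set")
}

## small genotype matrix from a plain integer matrix (samples x markers)
gm_from_matrix <- function(g, chrom = "chr1", pos = NULL) {
  g <- as.matrix(g)
  if (is.null(pos)) pos <- seq_len(ncol(g)) * 1000L
  genotype_matrix(
    sprintf("s%02d", seq_len(nrow(g))),
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
               stringsAsFactors = FALSE),
    g)
}

## brute-force oracle: maximal runs of concordant markers, one chromosome
brute_force_segments <- function(g, max_missing = 0L, min_markers = 1L,
                                 pos = seq_len(ncol(g)) * 1000L) {
  conc <- vapply(seq_len(ncol(g)), function(j) {
    col <- g[, j]
    n_na <- sum(is.na(col))
    obs <- col[!is.na(col)]
    length(obs) > 0 && n_na <= max_missing &&
      (all(obs == 0L) || all(obs == 2L))
  }, logical(1))
  runs <- list()
  j <- 1L
  while (j <= length(conc)) {
    if (conc[j]) {
      k <- j
      while (k < length(conc) && conc[k + 1L]) k <- k + 1L
      if (k - j + 1L >= min_markers)
        runs[[length(runs) + 1L]] <-
          data.frame(start_bp = pos[j], end_bp = pos[k],
                     n_markers = k - j + 1L)
      j <- k + 1L
    } else j <- j + 1L
  }
  if (!length(runs)) return(NULL)
  do.call(rbind, runs)
}
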