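#' @title Pedigree and haplotype simulation
#' @description Gene-drop simulation of a recessive allele descending from a
#'   single founder carrier, with per-position founder-origin labels so that
#'   identity-by-descent is known exactly (the truth layer every mapping test
#'   is checked against).
#' @name sim-population
NULL

## A haplotype_set is: list(ids, chroms = named list, each chromosome holding
##   pos (1-based bp), cm (map position), is_array (logical; FALSE for the
##   invisibly tracked causal locus), and four individuals x positions integer
##   matrices: h1/h2 (alleles, 0/1) and o1/o2 (founder-origin labels).

new_haplotype_set <- function(ids, chroms) {
  structure(list(ids = ids, chroms = chroms), class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  nm <- sum(vapply(x$chroms, function(ch) length(ch$pos), integer(1)))
  cat(sprintf("haplotype_set: %d individuals, %d chromosomes, %d positions\n",
              length(x$ids), length(x$chroms), nm))
  invisible(x)
}

#' Extract the genetic map of a haplotype set
#' @param haps a haplotype_set.
#' @return Named list per chromosome: data.frame(pos, cm).
#' @export
genetic_map <- function(haps) {
  lapply(haps$chroms, function(ch) data.frame(pos = ch$pos, cm = ch$cm))
}

## One meiosis on one chromosome under the Haldane model: crossover count is
## Poisson with mean = map length in Morgans, crossover locations uniform on
## the cM scale, no interference.
meiosis_gamete <- function(h1, h2, o1, o2, cm) {
  span <- cm[length(cm)] - cm[1]
  n_x <- stats::rpois(1L, span / 100)
  start <- sample.int(2L, 1L)
  if (n_x == 0L) {
    if (start == 1L) return(list(a = h1, o = o1)) else return(list(a = h2, o = o2))
  }
  xpos <- sort(stats::runif(n_x, cm[1], cm[length(cm)]))
  seg <- findInterval(cm, xpos)
  use1 <- (seg + start) %% 2L == 1L
  a <- h2; a[use1] <- h1[use1]
  o <- o2; o[use1] <- o1[use1]
  list(a = a, o = o)
}

#' Drop founder haplotypes through a pedigree
#'
#' Transmits founder haplotypes through every meiosis of a pedigree under the
#' Haldane crossover model (Poisson crossover count with mean equal to the map
#' length in Morgans, uniform locations, no interference) with fair Mendelian
#' segregation.  Founder-origin labels travel with the alleles, so
#' identity-by-descent is exact in the output.
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam` (NA for
#'   founders) and `generation`; parents must precede children.
#' @param map genetic map as returned by [genetic_map()]: per chromosome a
#'   data.frame with `pos` (bp) and `cm`.  Must cover every founder position.
#' @param founder_haps haplotype_set holding the founder rows.
#' @param seed integer seed.
#' @return A haplotype_set covering every pedigree member.
#' @export
gene_drop <- function(pedigree, map, founder_haps, seed = 1L) {
  set.seed(seed)
  ids <- pedigree$id
  founders <- is.na(pedigree$sire) & is.na(pedigree$dam)
  if (!all(pedigree$id[founders] %in% founder_haps$ids))
    stop("founder_haps must cover all pedigree founders")
  chroms <- vector("list", length(founder_haps$chroms))
  names(chroms) <- names(founder_haps$chroms)
  for (cn in names(founder_haps$chroms)) {
    fch <- founder_haps$chroms[[cn]]
    if (is.null(map[[cn]]) || !all(fch$pos %in% map[[cn]]$pos))
      stop("genetic map does not cover all markers on ", cn)
    cm <- map[[cn]]$cm[match(fch$pos, map[[cn]]$pos)]
    n <- length(ids); m <- length(fch$pos)
    h1 <- matrix(NA_integer_, n, m); h2 <- h1; o1 <- h1; o2 <- h1
    rownames(h1) <- rownames(h2) <- rownames(o1) <- rownames(o2) <- ids
    fidx <- match(pedigree$id[founders], founder_haps$ids)
    h1[founders, ] <- fch$h1[fidx, , drop = FALSE]
    h2[founders, ] <- fch$h2[fidx, , drop = FALSE]
    o1[founders, ] <- fch$o1[fidx, , drop = FALSE]
    o2[founders, ] <- fch$o2[fidx, , drop = FALSE]
    for (i in which(!founders)) {
      si <- match(pedigree$sire[i], ids)
      di <- match(pedigree$dam[i], ids)
      if (is.na(si) || is.na(di))
        stop("parent of ", ids[i], " not in pedigree")
      gs <- meiosis_gamete(h1[si, ], h2[si, ], o1[si, ], o2[si, ], cm)
      gd <- meiosis_gamete(h1[di, ], h2[di, ], o1[di, ], o2[di, ], cm)
      h1[i, ] <- gs$a; o1[i, ] <- gs$o
      h2[i, ] <- gd$a; o2[i, ] <- gd$o
    }
    chroms[[cn]] <- list(pos = fch$pos, cm = cm, is_array = fch$is_array,
                         h1 = h1, h2 = h2, o1 = o1, o2 = o2)
  }
  new_haplotype_set(ids, chroms)
}

## Founder haplotypes: biallelic array markers with per-marker allele
## frequencies ~ U(0.2, 0.8); the causal locus (chr1, not an array marker)
## carries allele 0 everywhere -- the causal allele is tracked purely through
## the origin label of founder 1's first haplotype.
make_founder_haplotypes <- function(ids, config, causal_pos) {
  n <- length(ids)
  chroms <- list()
  for (k in seq_along(config$chromosome_lengths)) {
    cn <- names(config$chromosome_lengths)[k]
    len <- config$chromosome_lengths[[k]]
    pos <- seq(config$marker_spacing, len, by = config$marker_spacing)
    is_array <- rep(TRUE, length(pos))
    if (k == 1L && !(causal_pos %in% pos)) {
      ins <- findInterval(causal_pos, pos)
      pos <- append(pos, causal_pos, after = ins)
      is_array <- append(is_array, FALSE, after = ins)
    } else if (k == 1L) {
      is_array[pos == causal_pos] <- FALSE
    }
    m <- length(pos)
    p <- stats::runif(m, 0.2, 0.8)
    h1 <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
    h2 <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
    h1[, !is_array] <- 0L; h2[, !is_array] <- 0L
    o1 <- matrix(rep(2L * (seq_len(n) - 1L) + 1L, m), n, m)
    o2 <- matrix(rep(2L * (seq_len(n) - 1L) + 2L, m), n, m)
    rownames(h1) <- rownames(h2) <- rownames(o1) <- rownames(o2) <- ids
    storage.mode(h1) <- "integer"; storage.mode(h2) <- "integer"
    chroms[[cn]] <- list(pos = pos, cm = pos / 1e6 * config$cm_per_mb,
                         is_array = is_array, h1 = h1, h2 = h2, o1 = o1, o2 = o2)
  }
  new_haplotype_set(ids, chroms)
}

#' Carrier state of each individual at the causal locus
#'
#' Counts, per individual, how many haplotypes descend from the causal
#' founder haplotype (origin label 1) at the tracked causal position.
#'
#' @param haps haplotype_set containing the causal chromosome.
#' @param causal_chrom,causal_pos location of the causal locus.
#' @return Integer vector (0 = noncarrier, 1 = carrier, 2 = homozygous),
#'   named by individual id.
#' @export
causal_copies <- function(haps, causal_chrom, causal_pos) {
  ch <- haps$chroms[[causal_chrom]]
  j <- match(causal_pos, ch$pos)
  if (is.na(j)) stop("causal position not tracked on ", causal_chrom)
  cc <- (ch$o1[, j] == 1L) + (ch$o2[, j] == 1L)
  names(cc) <- haps$ids
  cc
}

#' Simulate a pedigree segregating a founder-derived recessive allele
#'
#' Builds a multi-generation population in which exactly one founder (a
#' heavily used sire, emulating artificial insemination) is a heterozygous
#' carrier of the causal allele.  Later generations mate within the herd, so
#' both parental paths of every affected individual trace back to that
#' founder.  Phenotype follows a full-penetrance recessive model: affected
#' if and only if homozygous for the causal founder haplotype; affected
#' individuals do not breed (perinatal-lethal phenotype).  The whole
#' population is re-drawn (up to `config$max_attempts` times) until at least
#' `config$target_n_cases` affected individuals exist.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return A list of class `sim_population`: `pedigree` (data.frame with id,
#'   sire, dam, sex, generation, phenotype, carrier_state), `haplotypes`
#'   (haplotype_set with truth origin labels), `causal` (chrom/pos/founder),
#'   `gene` (the toy gene model), `cluster` (the causal codon cluster),
#'   `config`, `attempt`.
#' @export
build_population <- function(config = sim_config(), seed = config$seed) {
  gene <- make_toy_gene(seed = derive_seed(seed, 99L))
  cluster <- causal_cluster(gene)
  causal_pos <- cluster$genomic_positions[2]
  for (attempt in seq_len(config$max_attempts)) {
    set.seed(derive_seed(seed, attempt))
    pop <- sim_population_once(config, gene, cluster, causal_pos)
    n_aff <- sum(pop$pedigree$phenotype == "affected")
    if (n_aff >= config$target_n_cases) {
      pop$attempt <- attempt
      return(pop)
    }
  }
  stop(sprintf(
    "could not reach target_n_cases = %d affected within %d attempts (last attempt: %d)",
    config$target_n_cases, config$max_attempts, n_aff))
}

sim_population_once <- function(config, gene, cluster, causal_pos) {
  nf <- config$n_founders
  f_ids <- sprintf("G0_%03d", seq_len(nf))
  f_sex <- rep(c("M", "F"), length.out = nf)
  ped <- data.frame(id = f_ids, sire = NA_character_, dam = NA_character_,
                    sex = f_sex, generation = 0L, stringsAsFactors = FALSE)
  founder_haps <- make_founder_haplotypes(f_ids, config, causal_pos)
  ## founder 1 (male) is the sole carrier: origin label 1 is his first
  ## haplotype, and the causal allele rides on it by definition
  chroms <- founder_haps$chroms

  for (g in seq_len(config$n_generations)) {
    aff <- affected_ids(ped, chroms, causal_pos)
    if (g == 1L) {
      prev_m <- ped$id[ped$sex == "M" & ped$generation == 0L]
      prev_f <- ped$id[ped$sex == "F" & ped$generation == 0L]
    } else { # breed within the herd, not back to founders
      prev_m <- setdiff(ped$id[ped$sex == "M" & ped$generation > 0L], aff)
      prev_f <- setdiff(ped$id[ped$sex == "F" & ped$generation > 0L], aff)
    }
    if (!length(prev_m) || !length(prev_f)) break
    nm <- config$matings_per_generation
    sire <- sample(prev_m, nm, replace = TRUE)
    if (g == 1L) { # the carrier founder is a heavily used AI sire
      popular <- stats::runif(nm) < config$popular_sire_prob
      sire[popular] <- f_ids[1]
    }
    dam <- sample(prev_f, nm, replace = TRUE)
    n_off <- 1L + stats::rpois(nm, max(config$mean_offspring - 1, 0))
    new <- data.frame(
      id = NA_character_,
      sire = rep(sire, n_off), dam = rep(dam, n_off),
      sex = sample(c("M", "F"), sum(n_off), replace = TRUE),
      generation = g, stringsAsFactors = FALSE)
    new$id <- sprintf("G%d_%03d", g, seq_len(nrow(new)))
    ped <- rbind(ped, new)
    chroms <- drop_generation(ped, chroms, new$id)
  }

  haps <- new_haplotype_set(ped$id, chroms)
  cc <- causal_copies(haps, gene$chrom, causal_pos)
  ped$phenotype <- ifelse(cc[ped$id] == 2L, "affected", "unaffected")
  ped$carrier_state <- c("noncarrier", "carrier", "homozygous")[cc[ped$id] + 1L]
  structure(list(pedigree = ped, haplotypes = haps,
                 causal = list(chrom = gene$chrom, pos = causal_pos,
                               founder = f_ids[1]),
                 gene = gene, cluster = cluster, config = config),
            class = "sim_population")
}

## grow the haplotype matrices by the newly added children of one generation
drop_generation <- function(ped, chroms, new_ids) {
  idx_new <- match(new_ids, ped$id)
  for (cn in names(chroms)) {
    ch <- chroms[[cn]]
    n_old <- nrow(ch$h1); n_new <- length(new_ids); m <- length(ch$pos)
    grow <- function(x) {
      y <- rbind(x, matrix(NA_integer_, n_new, m))
      rownames(y) <- ped$id[seq_len(n_old + n_new)]
      y
    }
    h1 <- grow(ch$h1); h2 <- grow(ch$h2); o1 <- grow(ch$o1); o2 <- grow(ch$o2)
    for (i in idx_new) {
      si <- match(ped$sire[i], ped$id); di <- match(ped$dam[i], ped$id)
      gs <- meiosis_gamete(h1[si, ], h2[si, ], o1[si, ], o2[si, ], ch$cm)
      gd <- meiosis_gamete(h1[di, ], h2[di, ], o1[di, ], o2[di, ], ch$cm)
      h1[i, ] <- gs$a; o1[i, ] <- gs$o
      h2[i, ] <- gd$a; o2[i, ] <- gd$o
    }
    chroms[[cn]] <- list(pos = ch$pos, cm = ch$cm, is_array = ch$is_array,
                         h1 = h1, h2 = h2, o1 = o1, o2 = o2)
  }
  chroms
}

affected_ids <- function(ped, chroms, causal_pos) {
  ch <- chroms[[1L]]
  j <- match(causal_pos, ch$pos)
  done <- rownames(ch$o1)
  cc <- (ch$o1[, j] == 1L) + (ch$o2[, j] == 1L)
  done[cc == 2L]
}


#' True identical-by-descent autozygous segment shared by all affected
#'
#' Reads the founder-origin truth labels and returns the maximal contiguous
#' run of tracked positions around the causal locus over which every affected
#' individual is homozygous for the causal founder haplotype.
#'
#' @param pop a `sim_population`.
#' @return list(chrom, start_bp, end_bp) or NULL if there are no affected.
#' @export
truth_ibd_segment <- function(pop) {
  aff <- pop$pedigree$id[pop$pedigree$phenotype == "affected"]
  if (!length(aff)) return(NULL)
  ch <- pop$haplotypes$chroms[[pop$causal$chrom]]
  ai <- match(aff, pop$haplotypes$ids)
  homoz <- colSums(ch$o1[ai, , drop = FALSE] == 1L &
                   ch$o2[ai, , drop = FALSE] == 1L) == length(ai)
  j <- match(pop$causal$pos, ch$pos)
  if (!homoz[j]) stop("affected are not homozygous IBD at the causal locus")
  lo <- j; while (lo > 1L && homoz[lo - 1L]) lo <- lo - 1L
  hi <- j; while (hi < length(homoz) && homoz[hi + 1L]) hi <- hi + 1L
  list(chrom = pop$causal$chrom, start_bp = ch$pos[lo], end_bp = ch$pos[hi])
}
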