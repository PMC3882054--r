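test_that("a zero-generation config yields founders only and no affected", {
  cfg <- fast_config(n_generations = 0, target_n_cases = 0)
  pop <- build_population(cfg, seed = 7)
  expect_true(all(pop$pedigree$generation == 0L))
  expect_true(all(is.na(pop$pedigree$sire)))
  expect_identical(sum(pop$pedigree$phenotype == "affected"), 0L)
  expect_identical(pop$attempt, 1L)
})

test_that("an unreachable case quota fails naming the quota", {
  cfg <- fast_config(n_generations = 0, target_n_cases = 5, max_attempts = 3)
  expect_error(build_population(cfg, seed = 7), "target_n_cases = 5")
})

test_that("the default population matches its frozen golden run", {
  pop <- default_pop()
  ped <- pop$pedigree
  ## frozen from the first generation of this seed; regenerating the
  ## population must reproduce these exactly
  expect_identical(nrow(ped), 397L)
  expect_identical(sum(ped$phenotype == "affected"), 9L)
  expect_identical(sum(ped$carrier_state == "carrier"), 134L)
  ## and the run is deterministic
  pop2 <- build_population(sim_config(), seed = 42L)
  expect_identical(pop2$pedigree, ped)
  expect_identical(pop2$haplotypes$chroms$chr1$h1, pop$haplotypes$chroms$chr1$h1)
})

test_that("every affected is homozygous for the founder haplotype and has a
           paternal and a maternal path to the carrier founder", {
  pop <- default_pop()
  ped <- pop$pedigree
  copies <- causal_copies(pop$haplotypes, pop$causal$chrom, pop$causal$pos)
  expect_identical(unname(copies[ped$id] == 2L), ped$phenotype == "affected")
  descends <- function(id, via) {
    ## does founder `via` appear among the ancestors of id through parent links?
    repeat {
      if (id == via) return(TRUE)
      row <- ped[ped$id == id, ]
      if (is.na(row$sire)) return(FALSE)
      if (descends(row$sire, via) || descends(row$dam, via)) return(TRUE)
      return(FALSE)
    }
  }
  for (id in ped$id[ped$phenotype == "affected"]) {
    row <- ped[ped$id == id, ]
    expect_true(descends(row$sire, pop$causal$founder))
    expect_true(descends(row$dam, pop$causal$founder))
  }
})

test_that("no child carries an origin label absent from both parents", {
  pop <- default_pop()
  ped <- pop$pedigree
  haps <- pop$haplotypes
  for (cn in names(haps$chroms)) {
    ch <- haps$chroms[[cn]]
    kids <- which(!is.na(ped$sire))
    si <- match(ped$sire[kids], ped$id)
    di <- match(ped$dam[kids], ped$id)
    ## paternal haplotype labels must come from the sire, maternal from dam
    from_sire <- ch$o1[kids, ] == ch$o1[si, ] | ch$o1[kids, ] == ch$o2[si, ]
    from_dam <- ch$o2[kids, ] == ch$o1[di, ] | ch$o2[kids, ] == ch$o2[di, ]
    expect_true(all(from_sire))
    expect_true(all(from_dam))
  }
})

test_that("a zero-length genetic map transmits whole parental haplotypes", {
  ped <- trio_pedigree(20L)
  pos <- seq(1e5, 1e6, by = 1e5)
  alle <- matrix(rep(c(0L, 1L, 0L, 1L), each = length(pos)), 4,
                 byrow = TRUE)
  fh <- manual_founder_haps(c("S", "D"), pos, cm = rep(0, length(pos)),
                            alleles = alle)
  haps <- gene_drop(ped, genetic_map(fh), fh, seed = 3)
  ch <- haps$chroms$chr1
  for (kid in sprintf("C%03d", 1:20)) {
    expect_true(all(ch$o1[kid, ] == ch$o1[kid, 1]))  # unrecombined copy
    expect_true(all(ch$o2[kid, ] == ch$o2[kid, 1]))
  }
})

test_that("crossover count is Poisson with mean 1 on a 100-cM chromosome", {
  n_meioses <- 10000L
  ped <- trio_pedigree(n_meioses / 2L)
  pos <- seq_len(101L) * 1e6
  fh <- manual_founder_haps(c("S", "D"), pos, cm = seq(0, 100, by = 1))
  ## label switches along a gamete bound the realized crossover count from
  ## below; with 1-cM marker spacing double crossovers within an interval
  ## are rare (Haldane: ~0.00005 per interval), so the observed switch count
  ## estimates the Poisson mean
  haps <- gene_drop(ped, genetic_map(fh), fh, seed = 11)
  ch <- haps$chroms$chr1
  kid_rows <- grep("^C", haps$ids)
  switches <- function(o) sum(o[-1] != o[-length(o)])
  n_x <- c(apply(ch$o1[kid_rows, ], 1, switches),
           apply(ch$o2[kid_rows, ], 1, switches))
  se <- sqrt(1 / n_meioses)   # Poisson(1) variance = 1
  expect_gt(mean(n_x), 1 - 3 * se)
  expect_lt(mean(n_x), 1 + 3 * se)
})

test_that("carrier x noncarrier matings transmit the allele to half the offspring", {
  n_off <- 1200L
  ped <- trio_pedigree(n_off)
  pos <- seq(1e6, 30e6, by = 1e6)
  ## sire carries the tracked allele on haplotype 1 (origin label 1)
  fh <- manual_founder_haps(c("S", "D"), pos)
  haps <- gene_drop(ped, genetic_map(fh), fh, seed = 5)
  ch <- haps$chroms$chr1
  j <- 15L
  kid_rows <- grep("^C", haps$ids)
  carriers <- sum(ch$o1[kid_rows, j] == 1L | ch$o2[kid_rows, j] == 1L)
  p <- binom.test(carriers, n_off, 0.5)$p.value
  expect_gt(p, 0.01)  # within binomial 99% bounds of 0.5
})

test_that("array genotypes equal haplotype sums when error-free, and the
           error rate is realized at the configured frequency", {
  pop <- default_pop()
  gm0 <- emit_array_genotypes(pop$haplotypes, error_rate = 0, seed = 1)
  ch_truth <- lapply(pop$haplotypes$chroms, function(ch)
    (ch$h1 + ch$h2)[, ch$is_array, drop = FALSE])
  expect_identical(unname(gm0$geno), unname(do.call(cbind, ch_truth)))

  gm1 <- emit_array_genotypes(pop$haplotypes, error_rate = 0.01, seed = 1)
  n_calls <- length(gm1$geno)
  expect_gt(n_calls, 1e5)
  disc <- mean(gm1$geno != gm0$geno)
  expect_gt(disc, 0.008)
  expect_lt(disc, 0.012)
})

test_that("VCF and PED/MAP writes round-trip losslessly", {
  pop <- default_pop()
  gm <- emit_array_genotypes(pop$haplotypes, error_rate = 0.005, seed = 2,
                             samples = pop$haplotypes$ids[1:12])
  gm$geno[1, 3] <- NA  # exercise the missing-call path
  tmp <- withr::local_tempdir()
  vcf <- file.path(tmp, "g.vcf")
  write_vcf(gm, vcf)
  back <- read_vcf(vcf)
  expect_identical(back$samples, gm$samples)
  expect_equal(back$markers, gm$markers)
  expect_identical(unname(back$geno), unname(gm$geno))

  write_ped_map(gm, file.path(tmp, "g"))
  back2 <- read_ped_map(file.path(tmp, "g"))
  expect_equal(back2$markers, gm$markers)
  expect_identical(unname(back2$geno), unname(gm$geno))
})

test_that("WGS callset genotypes at the cluster follow true carrier state", {
  pop <- default_pop()
  wgs <- emit_wgs_callset(pop, seed = 3)
  keys <- variant_keys(wgs$callset)
  cl_idx <- match(wgs$cluster$genomic_positions, wgs$callset$markers$pos)
  expect_false(anyNA(cl_idx))
  g_cl <- wgs$callset$geno[, cl_idx, drop = FALSE]
  expect_true(all(g_cl[wgs$cohorts$cases, ] == 2L))
  expect_true(all(g_cl[wgs$cohorts$carriers, ] == 1L))
  expect_true(all(g_cl[wgs$cohorts$noncarriers, ] == 0L))
  ## the catalogue never contains the cluster
  expect_false(any(wgs$catalogue$pos %in% wgs$cluster$genomic_positions))
})

test_that("background variant count stays within Poisson 99% bounds", {
  pop <- default_pop()
  lam_kb <- pop$config$background_variant_density
  region_len <- NULL
  counts <- vapply(1:5, function(s) {
    w <- emit_wgs_callset(pop, seed = s)
    region_len <<- diff(w$region) + 1
    sum(w$truth$class == "background")
  }, numeric(1))
  lambda <- lam_kb * region_len / 1000
  lo <- qpois(0.005, lambda); hi <- qpois(0.995, lambda)
  expect_true(all(counts >= lo & counts <= hi))
  expect_gt(var(counts), 0)  # the count is drawn, not fixed
})

test_that("identical config and seed reproduce the WGS callset exactly", {
  pop <- default_pop()
  w1 <- emit_wgs_callset(pop, seed = 9)
  w2 <- emit_wgs_callset(pop, seed = 9)
  expect_identical(w1$callset$geno, w2$callset$geno)
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$catalogue, w2$catalogue)
})
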