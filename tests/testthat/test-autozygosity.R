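test_that("all-homozygous cases give one interval spanning the chromosome", {
  g <- matrix(2L, nrow = 3, ncol = 8)
  gm <- gm_from_matrix(g)
  seg <- shared_homozygosity_segments(gm, gm$samples, min_markers = 1)
  expect_identical(nrow(seg), 1L)
  expect_identical(seg$start_bp, 1000L)
  expect_identical(seg$end_bp, 8000L)
  expect_identical(seg$n_markers, 8L)
})

test_that("one heterozygous interior marker splits the run in two", {
  g <- matrix(2L, nrow = 3, ncol = 9)
  g[2, 5] <- 1L
  gm <- gm_from_matrix(g)
  seg <- shared_homozygosity_segments(gm, gm$samples, min_markers = 1)
  expect_identical(nrow(seg), 2L)
  expect_identical(seg$start_bp, c(1000L, 6000L))
  expect_identical(seg$end_bp, c(4000L, 9000L))
})

test_that("unknown case ids are rejected", {
  gm <- gm_from_matrix(matrix(0L, 2, 4))
  expect_error(shared_homozygosity_segments(gm, c("s01", "nope")), "nope")
})

test_that("segments match a brute-force oracle on random small matrices", {
  set.seed(404)
  for (rep in 1:60) {
    n <- sample(2:6, 1); m <- sample(3:20, 1)
    g <- matrix(sample(c(0L, 1L, 2L, NA), n * m, replace = TRUE,
                       prob = c(0.4, 0.2, 0.35, 0.05)), n, m)
    mm <- sample(0:1, 1); mk <- sample(1:3, 1)
    gm <- gm_from_matrix(g)
    got <- shared_homozygosity_segments(gm, gm$samples,
                                        max_missing_per_marker = mm,
                                        min_markers = mk)
    want <- brute_force_segments(g, max_missing = mm, min_markers = mk)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(got$start_bp, want$start_bp)
      expect_identical(got$end_bp, want$end_bp)
      expect_identical(got$n_markers, want$n_markers)
    }
  }
})

test_that("adding a case never lengthens a shared-homozygosity interval", {
  set.seed(505)
  for (rep in 1:20) {
    g <- matrix(sample(c(0L, 1L, 2L), 5 * 15, replace = TRUE,
                       prob = c(0.45, 0.1, 0.45)), 5, 15)
    gm <- gm_from_matrix(g)
    seg_few <- shared_homozygosity_segments(gm, gm$samples[1:3], min_markers = 1)
    seg_all <- shared_homozygosity_segments(gm, gm$samples, min_markers = 1)
    span <- function(s) if (nrow(s)) sum(s$n_markers) else 0L
    expect_lte(span(seg_all), span(seg_few))
  }
})

test_that("interval length uses end minus start scaled to Mb, 2 decimals", {
  expect_identical(
    interval_length_mb(list(start_bp = 632647, end_bp = 1781139)), 1.15)
  expect_identical(interval_length_mb(list(start_bp = 1, end_bp = 1000001)), 1)
  expect_identical(interval_length_mb(list(start_bp = 500, end_bp = 500)), 0)
  expect_error(interval_length_mb(list(start_bp = 2, end_bp = 1)))
})

test_that("a window with identical haplotype distributions scores zero", {
  ## two individuals, both with haplotypes {00, 11}, one affected
  fh <- manual_founder_haps(c("A", "B"), pos = c(1e6, 2e6),
                            alleles = rbind(c(0L, 0L), c(1L, 1L),
                                            c(0L, 0L), c(1L, 1L)))
  labels <- c(A = "affected", B = "unaffected")
  scan <- haplotype_window_scan(fh, labels, window_size = 2, step = 1,
                                min_count = 1)
  expect_identical(nrow(scan), 1L)
  expect_identical(scan$statistic, 0)
  expect_identical(scan$p, 1)
})

test_that("the scan statistic is invariant under allele relabeling", {
  set.seed(7)
  n <- 12
  alle <- matrix(sample(0:1, 2 * n * 10, replace = TRUE), 2 * n, 10)
  ids <- sprintf("i%02d", seq_len(n))
  fh <- manual_founder_haps(ids, pos = seq_len(10) * 1e5, alleles = alle)
  labels <- setNames(rep(c("affected", "unaffected"), each = n / 2), ids)
  s1 <- haplotype_window_scan(fh, labels, window_size = 3, step = 2)
  fh2 <- fh
  fh2$chroms$chr1$h1 <- 1L - fh$chroms$chr1$h1  # swap allele codes
  fh2$chroms$chr1$h2 <- 1L - fh$chroms$chr1$h2
  s2 <- haplotype_window_scan(fh2, labels, window_size = 3, step = 2)
  expect_equal(s1$statistic, s2$statistic)
  expect_equal(s1$p, s2$p)
})

test_that("on the default simulation the scan minimum and the IBS interval
           both localize the planted locus", {
  pop <- default_pop()
  ped <- pop$pedigree
  cases <- ped$id[ped$phenotype == "affected"]
  controls <- setdiff(ped$id, cases)[1:100]
  gm <- emit_array_genotypes(pop$haplotypes, error_rate = 0, seed = 1,
                             samples = c(cases, controls))
  seg <- shared_homozygosity_segments(gm, cases)
  truth <- truth_ibd_segment(pop)
  hit <- seg[seg$chrom == pop$causal$chrom &
             seg$start_bp <= pop$causal$pos &
             seg$end_bp >= pop$causal$pos, ]
  expect_identical(nrow(hit), 1L)
  ## the truth-IBD segment lies within the reported IBS interval
  expect_lte(hit$start_bp, truth$start_bp)
  expect_gte(hit$end_bp, truth$end_bp)

  labels <- setNames(ifelse(gm$samples %in% cases, "affected", "unaffected"),
                     gm$samples)
  scan <- haplotype_window_scan(pop$haplotypes, labels)
  top <- scan[which.min(scan$p), ]
  expect_identical(top$chrom, truth$chrom)
  expect_gte(top$end_bp, truth$start_bp)
  expect_lte(top$start_bp, truth$end_bp)
})

test_that("manhattan table has one row per window and round-trips", {
  fh <- manual_founder_haps(c("A", "B"), pos = c(1e6, 2e6),
                            alleles = rbind(c(0L, 0L), c(1L, 1L),
                                            c(0L, 0L), c(1L, 1L)))
  scan <- haplotype_window_scan(fh, c(A = "affected", B = "unaffected"),
                                window_size = 2, step = 1, min_count = 1)
  tab <- manhattan_table(scan)
  expect_identical(nrow(tab), nrow(scan))
  expect_identical(tab$neg_log10_p, 0)   # p = 1 window
  tmp <- withr::local_tempfile(fileext = ".tsv")
  manhattan_table(scan, tmp)
  back <- read.table(tmp, header = TRUE, sep = "\t")
  expect_equal(back, tab)
})

test_that("BED conversion is 0-based half-open on disk and round-trips", {
  iv <- data.frame(chrom = "chr25", start_bp = 632647L, end_bp = 1781139L,
                   n_markers = 57L)
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, tmp)
  raw <- read.table(tmp, sep = "\t")
  expect_identical(raw$V2, 632646L)   # start - 1
  expect_identical(raw$V3, 1781139L)  # end unchanged
  back <- read_bed(tmp)
  expect_equal(back, iv)
})
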