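## fixtures: a plus-strand toy gene and its mirrored minus-strand rendition
plus_gene <- make_toy_gene(seed = 11)

reverse_gene <- function(gene, genome_len = 40e6) {
  ## same transcript on the minus strand of a reverse-complemented genome:
  ## coordinates mirrored, CDS unchanged (it is strand-relative)
  mirror <- function(x) genome_len - x + 1L
  ex <- data.frame(start = mirror(gene$exons$end),
                   end = mirror(gene$exons$start))
  cds <- data.frame(start = mirror(gene$cds_spans$end),
                    end = mirror(gene$cds_spans$start))
  ord <- order(ex$start)
  structure(list(gene_id = gene$gene_id, chrom = gene$chrom, strand = "-",
                 exons = ex[ord, ], cds_spans = cds[ord, ],
                 cds_seq = gene$cds_seq,
                 tx_start = mirror(gene$tx_end), tx_end = mirror(gene$tx_start)),
            class = "toy_gene")
}

comp <- c(A = "T", C = "G", G = "C", T = "A")

test_that("codon arithmetic maps CDS positions to residue indices", {
  expect_identical(codon_index(2248), 750L)
  expect_identical(codon_index(2250), 750L)
  expect_identical(codon_index(2244), 748L)
  expect_identical(codon_index(c(1, 3, 4)), c(1L, 1L, 2L))
  expect_error(codon_index(0), ">= 1")
  expect_error(codon_index(2428, cds_length = 2427), "beyond")
})

test_that("the standard genetic code table matches Biostrings exactly", {
  codons <- names(Biostrings::GENETIC_CODE)
  for (cd in codons) {
    got <- translate_codon(cd)
    expect_identical(got$one, unname(Biostrings::GENETIC_CODE[cd]),
                     info = cd)
  }
  expect_identical(translate_codon("ATG"), list(one = "M", three = "Met"))
  expect_identical(translate_codon("TAC")$three, "Tyr")
  expect_identical(translate_codon("CAA")$three, "Gln")
  expect_identical(translate_codon("TAA")$one, "*")
  expect_error(translate_codon("ANT"), "invalid")
})

test_that("variants sharing a codon form one MNV group", {
  v <- data.frame(cds_pos = c(2244L, 2248L, 2250L),
                  ref = c("G", "T", "C"), alt = c("C", "C", "A"))
  gr <- group_codon_mnv(v)
  expect_length(gr, 2L)
  expect_identical(gr[[1]]$codon, 748L)
  expect_identical(gr[[1]]$members$cds_pos, 2244L)
  expect_identical(gr[[2]]$codon, 750L)
  expect_identical(gr[[2]]$members$cds_pos, c(2248L, 2250L))

  v3 <- data.frame(cds_pos = 1:3, ref = c("A", "T", "G"),
                   alt = c("C", "C", "C"))
  expect_length(group_codon_mnv(v3), 1L)
  expect_error(group_codon_mnv(rbind(v3, v3)), "duplicate")
})

test_that("grouping equals the brute-force same-codon closure on random sets", {
  set.seed(88)
  for (rep in 1:50) {
    k <- sample(1:6, 1)
    pos <- sort(sample(1:60, k))
    v <- data.frame(cds_pos = pos, ref = "A", alt = "C")
    gr <- group_codon_mnv(v)
    ## oracle: pairwise same-codon relation, transitively closed
    same <- outer(pos, pos, function(a, b) (a - 1) %/% 3 == (b - 1) %/% 3)
    oracle_groups <- unique(apply(same, 1, function(r) paste(pos[r], collapse = ",")))
    got_groups <- vapply(gr, function(g) paste(g$members$cds_pos, collapse = ","), "")
    expect_setequal(got_groups, oracle_groups)
  }
})

test_that("joint codon annotation gets the MNV consequence right where
           per-variant annotation would not", {
  cds <- plus_gene$cds_seq
  v <- data.frame(cds_pos = c(2248L, 2250L), ref = c("T", "C"),
                  alt = c("C", "A"))
  rec <- annotate_codon_group(group_codon_mnv(v)[[1]], cds)
  expect_identical(rec$ref_codon, "TAC")
  expect_identical(rec$alt_codon, "CAA")
  expect_identical(rec$class, "missense")
  expect_identical(rec$short_label, "Y750Q")
  expect_identical(rec$p_label, "p.Tyr750Gln")
  expect_setequal(rec$c_labels, c("c.2248T>C", "c.2250C>A"))

  silent <- data.frame(cds_pos = 2244L, ref = "G", alt = "C")
  rec2 <- annotate_codon_group(group_codon_mnv(silent)[[1]], cds)
  expect_identical(rec2$ref_codon, "TCG")
  expect_identical(rec2$alt_codon, "TCC")
  expect_identical(rec2$class, "synonymous")
  expect_identical(rec2$short_label, "S748")

  ## the same c.2250C>A substitution annotated alone is a spurious stop
  alone <- data.frame(cds_pos = 2250L, ref = "C", alt = "A")
  rec3 <- annotate_codon_group(group_codon_mnv(alone)[[1]], cds)
  expect_identical(rec3$alt_codon, "TAA")
  expect_identical(rec3$class, "nonsense")
  expect_false(identical(rec3$class, rec$class))
})

test_that("annotation refuses a ref allele that contradicts the CDS", {
  v <- data.frame(cds_pos = 2248L, ref = "G", alt = "C")
  expect_error(annotate_codon_group(group_codon_mnv(v)[[1]], plus_gene$cds_seq),
               "2248")
})

test_that("region classification matches a per-base oracle across an
           exon/intron boundary and respects 1-based inclusive limits", {
  g <- plus_gene
  expect_identical(classify_region(g$exons$start[1], g), "exonic-noncoding")
  expect_identical(classify_region(g$tx_start - 1L, g), "intergenic")
  expect_identical(classify_region(g$tx_end + 1L, g), "intergenic")

  ladder <- (g$exons$end[2] - 24L):(g$exons$end[2] + 25L)  # 50-bp ladder
  got <- classify_region(ladder, g)
  oracle <- vapply(ladder, function(p) {
    in_ex <- any(p >= g$exons$start & p <= g$exons$end)
    in_cds <- any(p >= g$cds_spans$start & p <= g$cds_spans$end)
    if (in_cds) "CDS" else if (in_ex) "exonic-noncoding"
    else if (p >= g$tx_start && p <= g$tx_end) "intronic" else "intergenic"
  }, "")
  expect_identical(got, oracle)
})

test_that("genomic/CDS coordinate maps are mutually inverse on both strands", {
  for (g in list(plus_gene, reverse_gene(plus_gene))) {
    cds_pos <- c(1L, 400L, 401L, 1500L, 2244L, 2248L, 2250L, 2427L)
    gp <- cds_to_genomic(g, cds_pos)
    expect_identical(genomic_to_cds(g, gp), cds_pos)
    expect_true(all(classify_region(gp, g) == "CDS"))
  }
})

test_that("a reverse-strand rendition of the gene annotates identically", {
  g <- plus_gene
  rg <- reverse_gene(g)
  cl <- causal_cluster(g)
  rcl <- causal_cluster(rg)
  ## same CDS-level cluster, mirrored genomic placement, complemented alleles
  expect_identical(rcl$cds_positions, cl$cds_positions)
  expect_identical(rcl$ref_genomic, unname(comp[cl$ref_genomic]))
  v_fwd <- variants_to_cds(g, rep(g$chrom, 3), cl$genomic_positions,
                           cl$ref_genomic, cl$alt_genomic)
  v_rev <- variants_to_cds(rg, rep(rg$chrom, 3), rcl$genomic_positions,
                           rcl$ref_genomic, rcl$alt_genomic)
  expect_identical(v_fwd, v_rev)
  rec_fwd <- lapply(group_codon_mnv(v_fwd), annotate_codon_group, g$cds_seq)
  rec_rev <- lapply(group_codon_mnv(v_rev), annotate_codon_group, rg$cds_seq)
  expect_identical(rec_fwd, rec_rev)
})

make_tiny_callset <- function() {
  ## 2 cases, 1 carrier, 2 controls; 4 hand-built variants
  samples <- c("ca1", "ca2", "cr1", "co1", "co2")
  markers <- data.frame(
    chrom = "chr1",
    pos = c(100L, 200L, 300L, 400L),
    ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"),
    stringsAsFactors = FALSE)
  geno <- rbind(             #     v1 v2 v3 v4
    ca1 = c(2L, 2L, 1L, 2L),
    ca2 = c(2L, 2L, 2L, 2L),
    cr1 = c(1L, 1L, 1L, 2L),
    co1 = c(0L, 1L, 0L, 0L),
    co2 = c(0L, 0L, 0L, 0L))
  genotype_matrix(samples, markers, geno)
}

test_that("the control/catalogue filter removes exactly the non-private", {
  gm <- make_tiny_callset()
  empty_cat <- data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character())
  ## variant 2 is het in control co1 -> removed even if not catalogued
  res <- filter_known_or_in_controls(gm, c("co1", "co2"), empty_cat)
  expect_identical(res$removed, 1L)
  expect_identical(res$retained$markers$pos, c(100L, 300L, 400L))
  ## empty catalogue, all controls hom-ref -> identity
  res2 <- filter_known_or_in_controls(gm, "co2", empty_cat)
  expect_identical(res2$removed, 0L)
  ## catalogue entry removes by key
  cat1 <- data.frame(chrom = "chr1", pos = 400L, ref = "T", alt = "C")
  res3 <- filter_known_or_in_controls(gm, "co2", cat1)
  expect_identical(res3$removed_keys, "chr1:400:T:C")
  expect_error(filter_known_or_in_controls(gm, "ghost", empty_cat), "ghost")
})

test_that("cascade B applies the three quantifiers and handles edge genotypes", {
  gm <- make_tiny_callset()
  gene <- plus_gene
  ## v1: hom cases, het carrier, absent controls -> survives
  ## v2: in control -> out; v3: ca1 het -> out; v4: carrier hom -> out
  rep <- cascade_b(gm, c("ca1", "ca2"), "cr1", c("co1", "co2"), gene)
  expect_identical(rep$survivors$pos, 100L)
  expect_identical(sum(rep$breakdown), 1L)
  expect_error(cascade_b(gm, c("ca1", "ca2"), "ca2", "co1", gene), "overlap")
  ## a missing case call disqualifies; a missing control call warns
  gm2 <- gm
  gm2$geno["ca1", 1] <- NA
  rep2 <- cascade_b(gm2, c("ca1", "ca2"), "cr1", c("co1", "co2"), gene)
  expect_identical(nrow(rep2$survivors), 0L)
  gm3 <- gm
  gm3$geno["co2", 1] <- NA
  expect_warning(
    rep3 <- cascade_b(gm3, c("ca1", "ca2"), "cr1", c("co1", "co2"), gene),
    "missing")
  expect_identical(rep3$survivors$pos, 100L)
})

test_that("cascade A on an empty callset and a fully catalogued callset", {
  gene <- plus_gene
  empty <- genotype_matrix(c("a", "b"),
                           data.frame(chrom = character(), pos = integer(),
                                      ref = character(), alt = character()),
                           matrix(integer(), 2, 0))
  rep0 <- cascade_a(empty, "a", "b",
                    data.frame(chrom = character(), pos = integer(),
                               ref = character(), alt = character()), gene)
  expect_true(all(rep0$counts == 0L))
  gm <- make_tiny_callset()
  allcat <- gm$markers
  rep100 <- cascade_a(gm, c("ca1", "ca2"), c("co1", "co2"), allcat, gene)
  expect_identical(rep100$percent_removed_step1, 100L)
  expect_identical(rep100$counts[["remaining"]], 0L)
})

test_that("cascades on the synthetic callset match the generator's truth
           bookkeeping and retain the causal cluster", {
  pop <- default_pop()
  wgs <- emit_wgs_callset(pop, seed = 5)
  tr <- wgs$truth
  rep_a <- cascade_a(wgs$callset, wgs$cohorts$cases, wgs$cohorts$noncarriers,
                     wgs$catalogue, wgs$gene)
  ## step-by-step counts from independent generator bookkeeping
  expect_identical(rep_a$counts[["total"]], nrow(tr))
  expect_identical(rep_a$counts[["removed_known_or_in_controls"]],
                   sum(tr$in_controls | tr$in_catalogue))
  expect_identical(rep_a$counts[["remaining"]],
                   sum(!(tr$in_controls | tr$in_catalogue)))
  priv <- !(tr$in_controls | tr$in_catalogue) & tr$hom_all_cases
  expect_identical(rep_a$counts[["hom_all_cases"]], sum(priv))
  expect_identical(rep_a$counts[["in_orf"]], sum(priv & tr$region == "CDS"))
  ## the aa-changing survivors are exactly the two codon-750 members
  cl <- wgs$cluster
  expect_setequal(
    rep_a$retained$aa_changing,
    paste("chr1", cl$genomic_positions[2:3], cl$ref_genomic[2:3],
          cl$alt_genomic[2:3], sep = ":"))

  rep_b <- cascade_b(wgs$callset, wgs$cohorts$cases, wgs$cohorts$carriers,
                     wgs$cohorts$noncarriers, wgs$gene)
  ## survivors = cluster + linked, partition sums hold
  expect_identical(nrow(rep_b$survivors), sum(tr$class != "background"))
  expect_identical(sum(rep_b$breakdown), nrow(rep_b$survivors))
  expect_identical(sum(rep_b$coding_split), unname(rep_b$breakdown["coding"]))
  expect_true(all(cl$genomic_positions %in% rep_b$survivors$pos))
  nonsyn <- Filter(function(r) r$class != "synonymous", rep_b$consequences)
  expect_length(nonsyn, 1L)
  expect_identical(nonsyn[[1]]$short_label, "Y750Q")
})

test_that("cascade results are invariant under input variant order", {
  pop <- default_pop()
  wgs <- emit_wgs_callset(pop, seed = 6)
  gm <- wgs$callset
  set.seed(1)
  perm <- sample(nrow(gm$markers))
  gm_shuffled <- genotype_matrix(gm$samples, gm$markers[perm, ],
                                 gm$geno[, perm])  # constructor re-sorts
  rep1 <- cascade_a(gm, wgs$cohorts$cases, wgs$cohorts$noncarriers,
                    wgs$catalogue, wgs$gene)
  rep2 <- cascade_a(gm_shuffled, wgs$cohorts$cases, wgs$cohorts$noncarriers,
                    wgs$catalogue, wgs$gene)
  expect_identical(rep1$counts, rep2$counts)
  expect_identical(rep1$retained, rep2$retained)
})

test_that("telescoping: each cascade-A step retains a subset of the previous", {
  pop <- default_pop()
  wgs <- emit_wgs_callset(pop, seed = 7)
  rep <- cascade_a(wgs$callset, wgs$cohorts$cases, wgs$cohorts$noncarriers,
                   wgs$catalogue, wgs$gene)
  cnt <- rep$counts
  expect_true(all(diff(cnt[c("remaining", "hom_all_cases", "in_transcribed",
                             "in_orf", "aa_changing")]) <= 0))
  expect_identical(cnt[["removed_known_or_in_controls"]] + cnt[["remaining"]],
                   cnt[["total"]])
  key_sets <- lapply(rep$retained[c("after_control_catalogue", "hom_all_cases",
                                    "transcribed", "orf")],
                     function(m) paste(m$chrom, m$pos, m$ref, m$alt, sep = ":"))
  for (i in 2:length(key_sets))
    expect_true(all(key_sets[[i]] %in% key_sets[[i - 1]]))
  expect_true(all(rep$retained$aa_changing %in% key_sets$orf))
})

test_that("gene model round-trips through GFF3 + FASTA", {
  tmp <- withr::local_tempdir()
  g <- plus_gene
  write_gene_gff3(g, file.path(tmp, "g.gff3"))
  write_cds_fasta(g, file.path(tmp, "g.fa"))
  back <- read_gene_gff3(file.path(tmp, "g.gff3"), file.path(tmp, "g.fa"))
  expect_identical(back$cds_seq, g$cds_seq)
  expect_equal(back$exons, g$exons)
  expect_equal(back$cds_spans, g$cds_spans)
  expect_identical(back$strand, g$strand)
  expect_identical(classify_region(15000000:15001000, back),
                   classify_region(15000000:15001000, g))
})
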