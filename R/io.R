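#' @title Readers and writers for the standard interchange formats
#' @description Genotypes travel as VCF v4.2 (GT only) or PED/MAP, intervals
#'   as BED (0-based half-open on disk, 1-based inclusive in memory), gene
#'   models as GFF3 + FASTA, voltage-clamp traces as TSV.
#' @name io
NULL

GT_STRINGS <- c("0/0", "0/1", "1/1")

#' Write a genotype matrix as a minimal multi-sample VCF v4.2
#'
#' Only the GT field is emitted; genotypes are written unphased.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=autozyg",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  gt <- matrix(GT_STRINGS[gm$geno + 1L], nrow = nrow(gm$geno))
  gt[is.na(gm$geno)] <- "./."
  body <- paste(gm$markers$chrom, gm$markers$pos,
                paste(gm$markers$chrom, gm$markers$pos,
                      gm$markers$ref, gm$markers$alt, sep = ":"),
                gm$markers$ref, gm$markers$alt, ".", "PASS", ".", "GT",
                apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parsing is delegated to `vcfR`; genotypes are recoded as alt-allele
#' counts.  Phased separators are accepted.
#'
#' @param path VCF file (optionally bgzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("\\|", "/", gt)
  counts[clean == "0/0"] <- 0L
  counts[clean %in% c("0/1", "1/0")] <- 1L
  counts[clean == "1/1"] <- 2L
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  markers <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                        ref = fix$REF, alt = fix$ALT,
                        stringsAsFactors = FALSE)
  genotype_matrix(colnames(gt), markers, t(counts))
}

#' Write a genotype matrix as a PED/MAP pair
#'
#' MAP marker ids are `chrom:pos:ref:alt`, which makes the pair lossless:
#' the reader recovers alt-allele counts from the id.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @param phenotype optional numeric phenotype column (default 0 = missing).
#' @return The prefix, invisibly.
#' @export
write_ped_map <- function(gm, prefix, phenotype = NULL) {
  mk <- gm$markers
  map <- data.frame(chrom = mk$chrom,
                    id = paste(mk$chrom, mk$pos, mk$ref, mk$alt, sep = ":"),
                    cm = mk$pos / 1e6, pos = mk$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- length(gm$samples); m <- nrow(mk)
  altm <- mk$alt[col(gm$geno)]
  a1 <- matrix(mk$ref[col(gm$geno)], n, m)
  a2 <- a1
  i1 <- which(gm$geno >= 1L); i2 <- which(gm$geno == 2L)
  a1[i1] <- altm[i1]; a2[i2] <- altm[i2]
  na <- which(is.na(gm$geno))
  a1[na] <- "0"; a2[na] <- "0"
  inter <- matrix("", n, 2L * m)
  inter[, seq(1L, 2L * m, 2L)] <- a1
  inter[, seq(2L, 2L * m, 2L)] <- a2
  if (is.null(phenotype)) phenotype <- rep(0L, n)
  ped <- cbind(gm$samples, gm$samples, "0", "0", "0", phenotype, inter)
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PED/MAP pair written by [write_ped_map()]
#'
#' @param prefix path prefix of the `.ped`/`.map` pair.
#' @return A [genotype_matrix()].
#' @export
read_ped_map <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           col.names = c("chrom", "id", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  key <- strsplit(map$id, ":", fixed = TRUE)
  markers <- data.frame(chrom = map$chrom, pos = map$pos,
                        ref = vapply(key, `[`, "", 3L),
                        alt = vapply(key, `[`, "", 4L),
                        stringsAsFactors = FALSE)
  ped <- utils::read.table(paste0(prefix, ".ped"), sep = " ",
                           colClasses = "character")
  samples <- ped[[2L]]
  m <- nrow(map)
  geno <- matrix(NA_integer_, nrow(ped), m)
  for (j in seq_len(m)) {
    a1 <- ped[[6L + 2L * j - 1L]]; a2 <- ped[[6L + 2L * j]]
    ok <- a1 != "0" & a2 != "0"
    geno[ok, j] <- (a1[ok] == markers$alt[j]) + (a2[ok] == markers$alt[j])
  }
  genotype_matrix(samples, markers, geno)
}

#' Write genomic intervals as BED
#'
#' In-memory intervals are 1-based inclusive; BED is 0-based half-open, so
#' `chromStart = start_bp - 1` and `chromEnd = end_bp`.
#'
#' @param intervals data.frame with `chrom`, `start_bp`, `end_bp` and
#'   optionally `n_markers` (stored in the name column).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  name <- if ("n_markers" %in% names(intervals))
    paste0("n_markers=", intervals$n_markers) else "."
  utils::write.table(
    data.frame(intervals$chrom, intervals$start_bp - 1L, intervals$end_bp, name),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file back to 1-based inclusive intervals
#' @param path BED file written by [write_bed()].
#' @return data.frame(chrom, start_bp, end_bp, n_markers).
#' @export
read_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t",
                         col.names = c("chrom", "start0", "end0", "name"),
                         colClasses = c("character", "integer", "integer",
                                        "character"))
  data.frame(chrom = b$chrom, start_bp = b$start0 + 1L, end_bp = b$end0,
             n_markers = suppressWarnings(
               as.integer(sub("n_markers=", "", b$name))),
             stringsAsFactors = FALSE)
}

#' Write a toy gene model as GFF3
#' @param gene a [make_toy_gene()] model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(gene, path) {
  g <- gene
  row <- function(type, s, e, id, parent = NULL) {
    attrs <- paste0("ID=", id,
                    if (!is.null(parent)) paste0(";Parent=", parent) else "")
    paste(g$chrom, "autozyg", type, s, e, ".", g$strand, ".", attrs,
          sep = "\t")
  }
  lines <- c("##gff-version 3",
             row("gene", g$tx_start, g$tx_end, g$gene_id),
             row("mRNA", g$tx_start, g$tx_end, paste0(g$gene_id, ".t1"),
                 g$gene_id))
  for (e in seq_len(nrow(g$exons)))
    lines <- c(lines, row("exon", g$exons$start[e], g$exons$end[e],
                          sprintf("%s.t1.exon%d", g$gene_id, e),
                          paste0(g$gene_id, ".t1")))
  for (e in seq_len(nrow(g$cds_spans)))
    lines <- c(lines, row("CDS", g$cds_spans$start[e], g$cds_spans$end[e],
                          sprintf("%s.t1.cds%d", g$gene_id, e),
                          paste0(g$gene_id, ".t1")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a toy gene model from GFF3 + CDS FASTA
#'
#' Uses `rtracklayer` for the GFF3 parsing.
#'
#' @param gff_path GFF3 with gene/mRNA/exon/CDS features of one transcript.
#' @param fasta_path FASTA holding the coding sequence.
#' @return A `toy_gene`.
#' @export
read_gene_gff3 <- function(gff_path, fasta_path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read GFF3")
  gr <- rtracklayer::import(gff_path, format = "gff3")
  df <- as.data.frame(gr)
  gene_row <- df[df$type == "gene", ][1L, ]
  ex <- df[df$type == "exon", c("start", "end")]
  cds <- df[df$type == "CDS", c("start", "end")]
  ex <- ex[order(ex$start), ]; cds <- cds[order(cds$start), ]
  rownames(ex) <- rownames(cds) <- NULL
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  structure(list(gene_id = gene_row$ID, chrom = as.character(gene_row$seqnames),
                 strand = as.character(gene_row$strand),
                 exons = ex, cds_spans = cds,
                 cds_seq = as.character(seqs[[1L]]),
                 tx_start = gene_row$start, tx_end = gene_row$end),
            class = "toy_gene")
}

#' Write the coding sequence as FASTA
#' @param gene a `toy_gene`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(gene, path) {
  s <- Biostrings::DNAStringSet(gene$cds_seq)
  names(s) <- paste0(gene$gene_id, ".t1.cds")
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Write a voltage-clamp trace as TSV
#'
#' Test-pulse samples go to `<path>`; the deactivation segment goes to a
#' companion file `<stem>_deact.tsv`.  Columns: `time_ms`, then one current
#' column per test voltage (`mV_<voltage>`).
#'
#' @param trace a `current_trace` from [simulate_traces()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  cols <- as.data.frame(trace$currents)
  names(cols) <- paste0("mV_", trace$protocol$test_voltages)
  utils::write.table(cbind(time_ms = trace$time_ms, cols), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dc <- as.data.frame(trace$deact_currents)
  names(dc) <- paste0("mV_", trace$protocol$test_voltages)
  stem <- sub("\\.tsv$", "", path)
  utils::write.table(cbind(time_ms = trace$deact_time_ms, dc),
                     paste0(stem, "_deact.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a voltage-clamp trace written by [write_trace()]
#' @param path TSV written by [write_trace()].
#' @param protocol the clamp protocol the trace was recorded under.
#' @return A `current_trace`.
#' @export
read_trace <- function(path, protocol = clamp_protocol()) {
  main <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE)
  stem <- sub("\\.tsv$", "", path)
  de <- utils::read.table(paste0(stem, "_deact.tsv"), sep = "\t",
                          header = TRUE, check.names = FALSE)
  volt <- as.numeric(sub("mV_", "", names(main)[-1L]))
  structure(list(protocol = protocol,
                 time_ms = main$time_ms,
                 currents = as.matrix(main[, -1L, drop = FALSE]),
                 deact_time_ms = de$time_ms,
                 deact_currents = as.matrix(de[, -1L, drop = FALSE]),
                 voltages = volt),
            class = "current_trace")
}

#' Write a per-sample genotype table as TSV
#'
#' Columns: sample, group, genotype (0/1/2, NA for missing) — the single-site
#' exchange format of the genotype-statistics stage.
#'
#' @param samples,groups,genotypes parallel vectors.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(samples, groups, genotypes, path) {
  utils::write.table(
    data.frame(sample = samples, group = groups, genotype = genotypes),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype table written by [write_genotype_table()]
#' @param path TSV with columns sample, group, genotype.
#' @return data.frame(sample, group, genotype).
#' @export
read_genotype_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "integer"))
  if (!all(c("sample", "group", "genotype") %in% names(tab)))
    stop("genotype table needs columns sample, group, genotype")
  tab
}
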