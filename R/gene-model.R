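#' @title Toy gene model and codon arithmetic
#' @description A minimal single-transcript gene model (exons, UTRs, CDS) with
#'   strand-aware mapping between genomic and CDS coordinates, used to plant
#'   and annotate the causal codon cluster.
#' @name gene-model
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct a toy gene with a 2427-bp ORF
#'
#' Five exons separated by 2-kb introns; the first exon carries a 200-bp
#' 5'UTR and the last a 300-bp 3'UTR.  The coding sequence is random over
#' non-stop codons except for the fixed landmarks: the start codon, codon 748
#' = TCG (Ser), codon 750 = TAC (Tyr) and a final stop.  Codons 748-750 fall
#' inside one exon, so the causal substitution cluster spans no intron.
#'
#' @param seed integer seed for the random codons.
#' @param chrom chromosome name.
#' @param gene_start 1-based genomic start of the transcript.
#' @param strand "+" or "-".
#' @param gene_id identifier.
#' @return A list of class `toy_gene`: `gene_id`, `chrom`, `strand`, `exons`
#'   (data.frame start/end, 1-based inclusive, genomic order), `cds_spans`
#'   (genomic spans of the coding part), `cds_seq` (2427-base string, coding
#'   strand), `tx_start`, `tx_end`.
#' @export
make_toy_gene <- function(seed = 99L, chrom = "chr1", gene_start = 15e6,
                          strand = "+", gene_id = "TOYG1") {
  set.seed(seed)
  gene_start <- as.integer(gene_start)
  n_codon <- 809L                      # 2427 / 3
  codons <- sample(setdiff(all_codons(), STOP_CODONS), n_codon, replace = TRUE)
  codons[1L] <- "ATG"
  codons[748L] <- "TCG"
  codons[750L] <- "TAC"
  codons[n_codon] <- "TAA"
  cds_seq <- paste(codons, collapse = "")

  utr5 <- 200L; utr3 <- 300L
  ## CDS bases carried by each exon (transcription order)
  cds_per_exon <- c(400L, 500L, 600L, 800L, 127L)
  exon_len <- cds_per_exon + c(utr5, 0L, 0L, 0L, utr3)
  intron_len <- 2000L
  tx_len <- sum(exon_len) + 4L * intron_len
  if (strand == "+") {
    starts <- gene_start + cumsum(c(0L, utils::head(exon_len, -1L) + intron_len))
    exons <- data.frame(start = starts, end = starts + exon_len - 1L)
    cds_spans <- exons
    cds_spans$start[1] <- exons$start[1] + utr5
    cds_spans$end[5] <- exons$end[5] - utr3
  } else {
    ## transcription runs right-to-left: exon 1 is the rightmost span
    ends <- gene_start + tx_len - 1L -
      cumsum(c(0L, utils::head(exon_len, -1L) + intron_len))
    exons <- data.frame(start = ends - exon_len + 1L, end = ends)
    cds_spans <- exons
    cds_spans$end[1] <- exons$end[1] - utr5
    cds_spans$start[5] <- exons$start[5] + utr3
    exons <- exons[5:1, ]; cds_spans <- cds_spans[5:1, ]   # genomic order
    rownames(exons) <- rownames(cds_spans) <- NULL
  }
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  cds_spans$start <- as.integer(cds_spans$start)
  cds_spans$end <- as.integer(cds_spans$end)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds_spans = cds_spans, cds_seq = cds_seq,
                 tx_start = min(exons$start), tx_end = max(exons$end)),
            class = "toy_gene")
}

#' @export
print.toy_gene <- function(x, ...) {
  cat(sprintf("toy_gene %s (%s%s): %d exons, CDS %d bp, span %s:%d-%d\n",
              x$gene_id, x$strand, "", nrow(x$exons), nchar(x$cds_seq),
              x$chrom, x$tx_start, x$tx_end))
  invisible(x)
}

## CDS spans ordered in transcription direction
cds_spans_tx_order <- function(gene) {
  sp <- gene$cds_spans
  if (gene$strand == "-") sp <- sp[rev(seq_len(nrow(sp))), , drop = FALSE]
  sp
}

#' Map CDS positions to genomic positions
#'
#' @param gene a [make_toy_gene()] model.
#' @param cds_pos vector of 1-based CDS base indices.
#' @return Integer vector of 1-based genomic positions.
#' @export
cds_to_genomic <- function(gene, cds_pos) {
  L <- nchar(gene$cds_seq)
  if (any(cds_pos < 1L | cds_pos > L))
    stop("CDS position out of range 1..", L)
  sp <- cds_spans_tx_order(gene)
  len <- sp$end - sp$start + 1L
  cum <- cumsum(len)
  ex <- findInterval(cds_pos - 1L, c(0L, cum), rightmost.closed = FALSE)
  off <- cds_pos - c(0L, cum)[ex] - 1L
  as.integer(if (gene$strand == "+") sp$start[ex] + off else sp$end[ex] - off)
}

#' Map genomic positions to CDS positions
#'
#' @param gene a [make_toy_gene()] model.
#' @param pos vector of 1-based genomic positions.
#' @return Integer vector of CDS positions; NA where the position is not
#'   coding.
#' @export
genomic_to_cds <- function(gene, pos) {
  sp <- cds_spans_tx_order(gene)
  len <- sp$end - sp$start + 1L
  cum0 <- c(0L, cumsum(len))
  out <- rep(NA_integer_, length(pos))
  for (e in seq_len(nrow(sp))) {
    inside <- pos >= sp$start[e] & pos <= sp$end[e]
    if (!any(inside)) next
    out[inside] <- as.integer(if (gene$strand == "+")
      cum0[e] + (pos[inside] - sp$start[e]) + 1L
    else
      cum0[e] + (sp$end[e] - pos[inside]) + 1L)
  }
  out
}

#' Classify a genomic position relative to a gene model
#'
#' 1-based inclusive boundaries throughout: a position on the first base of
#' an exon is exonic.
#'
#' @param pos vector of 1-based genomic positions.
#' @param gene a [make_toy_gene()] model.
#' @param chrom optional chromosome of each position; positions on another
#'   chromosome are intergenic.
#' @return Character vector over \{"intergenic", "intronic",
#'   "exonic-noncoding", "CDS"\}.
#' @export
classify_region <- function(pos, gene, chrom = NULL) {
  in_exon <- rep(FALSE, length(pos))
  for (e in seq_len(nrow(gene$exons)))
    in_exon <- in_exon | (pos >= gene$exons$start[e] & pos <= gene$exons$end[e])
  in_cds <- !is.na(genomic_to_cds(gene, pos))
  in_tx <- pos >= gene$tx_start & pos <= gene$tx_end
  out <- ifelse(in_cds, "CDS",
         ifelse(in_exon, "exonic-noncoding",
         ifelse(in_tx, "intronic", "intergenic")))
  if (!is.null(chrom)) out[chrom != gene$chrom] <- "intergenic"
  out
}

#' The planted causal codon cluster
#'
#' Three substitutions within 7 bp of one exon: CDS 2244 G>C (third base of
#' codon 748, silent), 2248 T>C and 2250 C>A (first and third base of codon
#' 750, jointly Tyr>Gln).  Ref alleles are read from the gene's CDS; genomic
#' positions and strand-aware genomic alleles are derived from the model.
#'
#' @param gene a [make_toy_gene()] model.
#' @return list of class `causal_cluster` with `chrom`, `cds_positions`,
#'   `genomic_positions`, `ref_alleles`/`alt_alleles` (coding strand) and
#'   `ref_genomic`/`alt_genomic` (reference strand).
#' @export
causal_cluster <- function(gene) {
  cds_pos <- c(2244L, 2248L, 2250L)
  ref <- substring(gene$cds_seq, cds_pos, cds_pos)
  stopifnot(identical(ref, c("G", "T", "C")))
  alt <- c("C", "C", "A")
  gpos <- cds_to_genomic(gene, cds_pos)
  ord <- order(gpos)
  if (max(gpos) - min(gpos) > 6L)
    stop("cluster spans more than 7 bp; exon layout broken")
  flip <- gene$strand == "-"
  structure(list(chrom = gene$chrom,
                 cds_positions = cds_pos,
                 genomic_positions = gpos,
                 ref_alleles = ref, alt_alleles = alt,
                 ref_genomic = if (flip) comp_base(ref) else ref,
                 alt_genomic = if (flip) comp_base(alt) else alt,
                 order_genomic = ord),
            class = "causal_cluster")
}

comp_base <- function(b) unname(c(A = "T", C = "G", G = "C", T = "A")[b])

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}
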