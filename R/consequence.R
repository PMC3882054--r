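#' @title Codon-aware (MNV) consequence annotation
#' @description Substitutions falling in the same codon must be applied
#'   jointly before translation: annotating each separately can turn a
#'   missense multi-nucleotide variant into a spurious nonsense call (or vice
#'   versa).  These functions group coding substitutions by codon and
#'   annotate each group as a unit.
#' @name consequence
NULL

## Standard genetic code, one-letter amino acids; "*" = stop.
CODON_TABLE_1 <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              "*" = "Ter")

#' Translate one codon under the standard genetic code
#'
#' @param codon 3-base string over A/C/G/T.
#' @return list(one = one-letter amino acid ("*" for stop),
#'   three = three-letter code ("Ter" for stop)).
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("invalid codon: ", codon)
  one <- unname(CODON_TABLE_1[codon])
  list(one = one, three = unname(AA_THREE[one]))
}

#' Codon (residue) index of a CDS base position
#'
#' 1-based on both sides: bases 1-3 are codon 1.
#'
#' @param cds_position 1-based base index into the coding sequence.
#' @param cds_length optional CDS length for range checking.
#' @return Integer codon index.
#' @export
codon_index <- function(cds_position, cds_length = NULL) {
  if (any(cds_position < 1L))
    stop("CDS position must be >= 1")
  if (!is.null(cds_length) && any(cds_position > cds_length))
    stop("CDS position beyond CDS length ", cds_length)
  ((as.integer(cds_position) - 1L) %/% 3L) + 1L
}

#' Group coding substitutions into per-codon (MNV) groups
#'
#' Variants sharing a codon index form one group; all others are singletons.
#'
#' @param cds_variants data.frame with columns `cds_pos`, `ref`, `alt`
#'   (coding-strand alleles).
#' @param cds_length optional CDS length for range checking.
#' @return List of `codon_group` objects: `codon` (index), `members`
#'   (data.frame cds_pos/ref/alt/offset, offset = 0-2 within the codon),
#'   ordered by codon index.
#' @export
group_codon_mnv <- function(cds_variants, cds_length = NULL) {
  stopifnot(all(c("cds_pos", "ref", "alt") %in% names(cds_variants)))
  if (anyDuplicated(cds_variants$cds_pos))
    stop("duplicate CDS position in variant set")
  ci <- codon_index(cds_variants$cds_pos, cds_length)
  out <- lapply(sort(unique(ci)), function(k) {
    mem <- cds_variants[ci == k, , drop = FALSE]
    mem <- mem[order(mem$cds_pos), , drop = FALSE]
    mem$offset <- (mem$cds_pos - 1L) %% 3L
    rownames(mem) <- NULL
    structure(list(codon = k, members = mem), class = "codon_group")
  })
  out
}

#' Annotate one codon group jointly
#'
#' Applies all member substitutions to the reference codon simultaneously,
#' translates reference and mutated codon, classifies the change and emits
#' HGVS-like labels (c.2248T>C; p.Tyr750Gln; Y750Q).
#'
#' @param group a `codon_group` from [group_codon_mnv()].
#' @param cds_seq coding sequence string; member ref alleles must match it.
#' @return list of class `consequence_record`: codon index, ref/alt codon,
#'   ref/alt amino acid (1- and 3-letter), `class` in \{synonymous, missense,
#'   nonsense, stop-loss\}, `c_labels`, `p_label`, `short_label`.
#' @export
annotate_codon_group <- function(group, cds_seq) {
  mem <- group$members
  k <- group$codon
  ref_codon <- substring(cds_seq, 3L * (k - 1L) + 1L, 3L * k)
  obs <- substring(cds_seq, mem$cds_pos, mem$cds_pos)
  bad <- obs != mem$ref
  if (any(bad))
    stop("ref allele mismatch with CDS at position(s) ",
         paste(mem$cds_pos[bad], collapse = ", "),
         " (CDS has ", paste(obs[bad], collapse = ", "), ")")
  alt_codon <- ref_codon
  for (i in seq_len(nrow(mem)))
    substr(alt_codon, mem$offset[i] + 1L, mem$offset[i] + 1L) <- mem$alt[i]
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  cls <- if (ref_aa$one == alt_aa$one) "synonymous"
         else if (alt_aa$one == "*") "nonsense"
         else if (ref_aa$one == "*") "stop-loss"
         else "missense"
  structure(list(
    codon = k, ref_codon = ref_codon, alt_codon = alt_codon,
    ref_aa = ref_aa$one, alt_aa = alt_aa$one,
    ref_aa3 = ref_aa$three, alt_aa3 = alt_aa$three,
    class = cls,
    c_labels = sprintf("c.%d%s>%s", mem$cds_pos, mem$ref, mem$alt),
    p_label = if (cls == "synonymous") sprintf("p.%s%d=", ref_aa$three, k)
              else sprintf("p.%s%d%s", ref_aa$three, k, alt_aa$three),
    short_label = if (cls == "synonymous") sprintf("%s%d", ref_aa$one, k)
                  else sprintf("%s%d%s", ref_aa$one, k, alt_aa$one)),
    class = "consequence_record")
}

#' @export
print.consequence_record <- function(x, ...) {
  cat(sprintf("codon %d: %s>%s (%s>%s) %s [%s] %s\n",
              x$codon, x$ref_codon, x$alt_codon, x$ref_aa, x$alt_aa,
              x$class, paste(x$c_labels, collapse = " + "), x$p_label))
  invisible(x)
}

#' Project genomic substitutions onto CDS coordinates
#'
#' Strand-aware: on a minus-strand gene, coding-strand alleles are the
#' complements of the reference-strand alleles.
#'
#' @param gene a [make_toy_gene()] model.
#' @param chrom,pos,ref,alt parallel vectors describing substitutions on the
#'   reference strand.
#' @return data.frame(cds_pos, ref, alt) restricted to CDS substitutions
#'   (single-base ref and alt), in CDS order.
#' @export
variants_to_cds <- function(gene, chrom, pos, ref, alt) {
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & chrom == gene$chrom
  cp <- genomic_to_cds(gene, pos)
  keep <- snv & !is.na(cp)
  ref <- ref[keep]; alt <- alt[keep]; cp <- cp[keep]
  if (gene$strand == "-") {
    ref <- unname(comp_base(ref)); alt <- unname(comp_base(alt))
  }
  out <- data.frame(cds_pos = cp, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  out[order(out$cds_pos), , drop = FALSE]
}
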