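#' Samples-by-markers genotype container
#'
#' The central genotype container used by the mapping and prioritization
#' stages: a marker table (chromosome, 1-based bp position, ref/alt alleles)
#' plus an integer genotype matrix coded as copies of the alt allele
#' (0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing call).
#'
#' @param samples character vector of sample ids (rows of `geno`).
#' @param markers data.frame with columns `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`; rows must be sorted by chromosome then position.
#' @param geno integer matrix, `length(samples)` x `nrow(markers)`, values
#'   in \{0, 1, 2, NA\}.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, markers, geno) {
  stopifnot(is.character(samples), is.data.frame(markers))
  needed <- c("chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(markers)))
    stop("markers must have columns: ", paste(needed, collapse = ", "))
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != length(samples) || ncol(geno) != nrow(markers))
    stop("geno must be length(samples) x nrow(markers)")
  bad <- !(geno %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  markers$pos <- as.integer(markers$pos)
  ord <- order(as.character(markers$chrom), markers$pos)
  if (!identical(ord, seq_len(nrow(markers)))) {
    markers <- markers[ord, , drop = FALSE]
    geno <- geno[, ord, drop = FALSE]
  }
  rownames(geno) <- samples
  rownames(markers) <- NULL
  structure(list(samples = samples, markers = markers, geno = geno),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%d chromosome(s))\n",
              length(x$samples), nrow(x$markers),
              length(unique(x$markers$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by sample ids and/or marker index
#'
#' @param gm a [genotype_matrix()].
#' @param samples character vector of sample ids to keep (default all).
#' @param markers integer/logical index into marker rows (default all).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, samples = NULL, markers = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(samples)) samples <- gm$samples
  miss <- setdiff(samples, gm$samples)
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  if (is.null(markers)) markers <- seq_len(nrow(gm$markers))
  genotype_matrix(samples,
                  gm$markers[markers, , drop = FALSE],
                  gm$geno[match(samples, gm$samples), markers, drop = FALSE])
}

#' Marker key strings ("chrom:pos:ref:alt") for a genotype matrix
#' @param gm a [genotype_matrix()].
#' @return character vector, one key per marker.
#' @export
variant_keys <- function(gm) {
  with(gm$markers, paste(chrom, pos, ref, alt, sep = ":"))
}
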