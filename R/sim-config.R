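#' Simulation configuration for the synthetic population
#'
#' Bundles every knob of the synthetic-data generator.  Defaults give a
#' desk-scale population emulating the study design of a recessive lethal
#' allele descending from a single popular sire in a closed beef-cattle
#' herdbook: three 30-Mb chromosomes at one array marker per 30 kb
#' (a reduced stand-in for a 50K array), a founder generation containing
#' exactly one heterozygous carrier, and a whole-genome-sequenced subset of
#' 4 cases, 6 carriers and 8 non-carriers around a toy gene with a 2427-bp
#' ORF.
#'
#' @param n_founders number of founder individuals (>= 4).
#' @param n_generations number of bred generations after the founders.
#' @param mean_offspring mean litter size per mating (Poisson, zero-truncated).
#' @param popular_sire_prob fraction of first-generation matings sired by the
#'   carrier founder (the artificial-insemination popular-sire effect that
#'   lets a recessive allele sweep through a closed herdbook).
#' @param matings_per_generation number of matings arranged per generation.
#' @param target_n_cases minimum number of affected individuals the
#'   population must contain; the generator re-draws (bounded attempts) until
#'   the quota is met.
#' @param max_attempts bound on re-draws before failing.
#' @param chromosome_lengths named or unnamed vector of chromosome lengths, bp.
#' @param marker_spacing array marker spacing, bp.
#' @param cm_per_mb genetic-map density (centimorgan per megabase).
#' @param genotyping_error_rate probability an emitted array genotype is
#'   replaced by a random different genotype.
#' @param background_variant_density WGS background variants per kb over the
#'   sequenced region.
#' @param catalogue_fraction probability a non-linked background variant is in
#'   the known-variants catalogue.
#' @param p_in_controls probability a background variant is segregating in the
#'   control cohort (and therefore removable as non-private).
#' @param n_linked_intergenic,n_linked_intronic,n_linked_synonymous numbers of
#'   variants planted in perfect co-segregation with the disease haplotype
#'   (besides the causal codon cluster), by region class.
#' @param region_flank bp of sequenced region on each side of the toy gene.
#' @param n_wgs_cases,n_wgs_carriers,n_wgs_noncarriers WGS cohort sizes.
#' @param n_array_controls unaffected individuals genotyped on the array.
#' @param seed default integer seed used when an operation is not given one.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 40,
                       n_generations = 3,
                       mean_offspring = 3,
                       popular_sire_prob = 0.75,
                       matings_per_generation = 40,
                       target_n_cases = 6,
                       max_attempts = 50,
                       chromosome_lengths = c(chr1 = 30e6, chr2 = 30e6, chr3 = 30e6),
                       marker_spacing = 30000,
                       cm_per_mb = 1,
                       genotyping_error_rate = 0.001,
                       background_variant_density = 1.9,
                       catalogue_fraction = 0.2,
                       p_in_controls = 0.8,
                       n_linked_intergenic = 8,
                       n_linked_intronic = 3,
                       n_linked_synonymous = 2,
                       region_flank = 5e5,
                       n_wgs_cases = 4,
                       n_wgs_carriers = 6,
                       n_wgs_noncarriers = 8,
                       n_array_controls = 100,
                       seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  if (is.null(names(cfg$chromosome_lengths)))
    names(cfg$chromosome_lengths) <- paste0("chr", seq_along(cfg$chromosome_lengths))
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_founders", "mean_offspring",
              "matings_per_generation", "max_attempts", "marker_spacing",
              "n_wgs_cases", "n_wgs_carriers", "n_wgs_noncarriers",
              "n_array_controls")
  for (f in counts)
    if (cfg[[f]] < 1) stop(f, " must be >= 1")
  if (cfg$target_n_cases < 0) stop("target_n_cases must be >= 0")
  if (cfg$n_generations < 0) stop("n_generations must be >= 0")
  probs <- c("genotyping_error_rate", "catalogue_fraction", "p_in_controls",
             "popular_sire_prob")
  for (f in probs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  if (cfg$cm_per_mb < 0) stop("cm_per_mb must be >= 0")
  if (any(cfg$chromosome_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (cfg$background_variant_density < 0)
    stop("background_variant_density must be >= 0")
  invisible(TRUE)
}

#' Derive a stream-specific 32-bit seed from a master seed
#'
#' Deterministic, keeps every derived seed strictly below 2^31 so it is a
#' valid R integer.
#'
#' @param seed master integer seed.
#' @param stream small non-negative integer identifying the consumer.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647)
}
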