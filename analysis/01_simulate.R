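#!/usr/bin/env Rscript
## Stage 1 -- simulate the study population.
##
## Builds a three-generation herd descending from a single heterozygous
## carrier sire, emits SNP-array genotypes for all affected calves plus 100
## unaffected controls, and emits a WGS-like callset (4 cases, 6 carriers,
## 8 non-carrier controls) around a toy gene with a 2427-bp ORF carrying the
## planted 3-substitution causal cluster in one codon neighbourhood.
## All downstream stages read these files from results/pipeline/.

suppressPackageStartupMessages(library(autozyg))

out_dir <- "results/pipeline"
cfg <- run_config(seed = 1)
sim <- run_stage("simulate", cfg, out_dir = {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE); out_dir
})
dir.create("scratch", showWarnings = FALSE)
saveRDS(sim, "scratch/state_simulate.rds")  # working state for later stages

ped <- sim$pop$pedigree
cat(sprintf("population: %d individuals over %d generations\n",
            nrow(ped), max(ped$generation)))
cat(sprintf("affected calves: %d (all homozygous for the founder haplotype)\n",
            sum(ped$phenotype == "affected")))
cat(sprintf("carriers: %d\n", sum(ped$carrier_state == "carrier")))
cat(sprintf("WGS callset: %d variants over %s:%d-%d\n",
            nrow(sim$wgs$callset$markers), sim$wgs$gene$chrom,
            sim$wgs$region[1], sim$wgs$region[2]))
cat(sprintf("planted cluster at %s:%d-%d (CDS %s)\n",
            sim$wgs$cluster$chrom, min(sim$wgs$cluster$genomic_positions),
            max(sim$wgs$cluster$genomic_positions),
            paste(sim$wgs$cluster$cds_positions, collapse = "/")))
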