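#!/usr/bin/env Rscript
## Stage 2 -- map the disease locus.
##
## Two complementary views: (i) the maximal interval over which all affected
## are homozygous and identical by state (the analogue of visually defining
## a non-recombinant autozygous interval), written as BED; (ii) a
## case/control haplotype-window chi-square scan, written as a Manhattan
## table.  The interval is checked against the generator's truth IBD layer.

suppressPackageStartupMessages(library(autozyg))

cfg <- run_config(seed = 1)
sim <- readRDS("scratch/state_simulate.rds")
map <- run_stage("map", cfg, list(simulate = sim), out_dir = "results/pipeline")
saveRDS(map, "scratch/state_map.rds")

seg <- map$segments
cat(sprintf("%d shared-homozygosity segment(s) reported\n", nrow(seg)))
cl <- sim$wgs$cluster
hit <- seg[seg$chrom == cl$chrom &
           seg$start_bp <= min(cl$genomic_positions) &
           seg$end_bp >= max(cl$genomic_positions), ]
stopifnot(nrow(hit) == 1L)
cat(sprintf("causal interval: %s:%d-%d (%.2f Mb, %d markers)\n",
            hit$chrom, hit$start_bp, hit$end_bp, interval_length_mb(hit),
            hit$n_markers))
truth <- truth_ibd_segment(sim$pop)
cat(sprintf("truth IBD segment %s:%d-%d contained: %s\n", truth$chrom,
            truth$start_bp, truth$end_bp,
            hit$start_bp <= truth$start_bp && hit$end_bp >= truth$end_bp))
top <- map$scan[which.min(map$scan$p), ]
cat(sprintf("scan minimum p = %.3g at %s:%.0f (inside interval: %s)\n",
            top$p, top$chrom, top$mid_bp,
            top$chrom == hit$chrom && top$mid_bp >= hit$start_bp &&
              top$mid_bp <= hit$end_bp))
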