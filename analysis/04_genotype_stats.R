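#!/usr/bin/env Rscript
## Stage 4 -- population-genetic checks.
##
## (i) Hardy-Weinberg on the simulated unaffected cohort (a deficit of
## mutant homozygotes is the expected signature of a perinatal-lethal
## recessive); (ii) the same test on the published-scale control counts
## (5845 hom-ref / 644 het / 0 hom-alt), where the Pearson form reproduces
## p = 0.000026; (iii) full recessive-segregation verification against the
## pedigree.

suppressPackageStartupMessages(library(autozyg))

cfg <- run_config(seed = 1)
sim <- readRDS("scratch/state_simulate.rds")
st <- run_stage("stats", cfg, list(simulate = sim))
saveRDS(st, "scratch/state_stats.rds")

cc <- st$control_counts
cat(sprintf("simulated unaffected cohort: %d hom-ref / %d het / %d hom-alt\n",
            cc[1], cc[2], cc[3]))
cat(sprintf("  HWE (Pearson, df 1): chi2 = %.2f, p = %.3g\n",
            st$hwe$statistic, st$hwe$p))
cat(sprintf("  allele frequency: %.2f%% (%s)\n",
            st$allele_freq$percent, st$allele_freq$rendered))
print(st$segregation)

ref <- hwe_test(5845, 644, 0)
fr <- allele_frequency_percent(5845, 644, 0)
cat(sprintf("\ncontrol-cohort counts 5845/644/0: chi2 = %.2f, p = %.6f, allele freq %s\n",
            ref$statistic, ref$p, fr$rendered))
jsonlite::write_json(
  list(simulated = list(counts = as.list(cc), hwe_p = st$hwe$p,
                        allele_pct = st$allele_freq$percent,
                        segregation_pass = st$segregation$pass),
       control_cohort = list(chi2 = ref$statistic, p = ref$p,
                             allele_pct = fr$percent)),
  "results/genotype_stats.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
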