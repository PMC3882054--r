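# autozyg

Recessive-disease gene discovery for a founder-derived lethal allele, as a
tested R workflow: autozygosity mapping from SNP-array genotypes,
private-variant prioritization over whole-genome callsets with codon-aware
multi-nucleotide variant (MNV) annotation, Hardy–Weinberg and segregation
statistics, and voltage-clamp gating-kinetics analysis.  Everything runs
against a synthetic-data generator with exact identity-by-descent ground
truth, so each stage is verifiable end to end.

## Who this is for

Anyone who needs the machinery of a livestock (or other closed-population)
recessive-defect study in testable form: a pedigree/gene-drop simulator with
a single founder carrier, exact shared-homozygosity interval detection, a
haplotype-window association scan, the two classic variant-filtering
cascades (private-vs-controls/catalogue, and case-hom/carrier-het/control-
absent), and single-exponential fitting of two-electrode voltage-clamp
(TEVC) current traces.

## The methods in brief

- **Mapping.** A marker is concordant when all cases are homozygous for the
  same allele; maximal concordant runs are the candidate autozygous
  intervals, with length `(end − start)/10⁶` Mb (so chr25:632,647–1,781,139
  is 1.15 Mb).  A windowed Pearson chi-square over pooled haplotype classes
  (haplotype × phenotype table over chromosomes) provides the genome-wide
  scan.
- **Prioritization.** Cascade A: drop variants seen in controls or in a
  known catalogue, keep hom-alt-in-all-cases, then transcribed → ORF →
  amino-acid-changing.  Cascade B: keep variants hom-alt in all cases, het
  in all carriers, absent in all non-carriers, and break survivors down by
  region.  Substitutions sharing a codon are annotated **jointly**: the
  cluster c.2244G>C + c.2248T>C + c.2250C>A in a 2427-bp ORF yields a silent
  S748 (TCG>TCC) plus the missense Y750Q (TAC>CAA), where naive per-variant
  annotation would miscall a nonsense TAC>TAA.
- **Statistics.** Hardy–Weinberg as the Pearson chi-square on genotype
  counts (df 1, no continuity correction; q̂ estimated from the data):
  counts (5845, 644, 0) give χ² = 17.7, p = 0.000026 — a deficit of 16
  expected mutant homozygotes, the signature of a recessive lethal.  Allele
  vs carrier frequency is kept explicit: 644/(2·6489) = 4.96% ≈ "5%".
- **Kinetics.** Test-pulse currents are fitted with
  I(t) = I_ss − ΔI·e^(−t/τ) over the first 250 ms at +80 mV; groups of
  fitted τ are compared with an equal-variance t-test and a fold ratio.

## Worked example

The `analysis/` scripts run the whole study in order; each is a thin driver
over the package functions and writes its tables under `results/`.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_map.R
Rscript analysis/03_prioritize.R
Rscript analysis/04_genotype_stats.R
Rscript analysis/05_kinetics.R
```

Output of a run at seed 1 (abridged):

```
population: 404 individuals over 3 generations
affected calves: 7 (all homozygous for the founder haplotype)
planted cluster at chr1:15008443-15008449 (CDS 2244/2248/2250)

causal interval: chr1:13440000-15900000 (2.46 Mb, 83 markers)
truth IBD segment chr1:13590000-15900000 contained: TRUE
scan minimum p = 8.59e-16 at chr1:13665000 (inside interval: TRUE)

Cascade A: 1994 -> 170 -> 16 -> 5 -> 5 -> 2 (91% removed at step 1)
Cascade B: 16 survivors (8 intergenic, 3 intronic, 5 coding; 3 syn, 2 non-syn)
unique non-synonymous cascade-B survivor:
codon 750: TAC>CAA (Y>Q) missense [c.2248T>C + c.2250C>A] p.Tyr750Gln

simulated unaffected cohort: 268 hom-ref / 129 het / 0 hom-alt
  HWE (Pearson, df 1): chi2 = 14.94, p = 0.000111
Recessive segregation check: PASS

WT:  tau = 346 +/- 22 ms (n = 13)
MUT: tau = 113 +/- 6 ms (n = 18)
fold acceleration: 3.1; t = 11.8 (df 29), p = 1.4e-12
```

Reading this: all affected calves share one homozygous identical-by-state
interval that contains (and bounds) the true identical-by-descent segment
around the planted locus; of 1,994 called variants only the three-substitution
cluster plus its privately linked neighbourhood survive the segregation
filter, and joint codon annotation identifies Y750Q as the sole
non-synonymous survivor; the unaffected cohort shows the homozygote deficit
expected for a perinatal-lethal recessive; and the mutant's activation time
constant is accelerated more than three-fold at overwhelming significance.

The same thing as one call:

```r
library(autozyg)
rep <- run_all(run_config(seed = 1), out_dir = "results/pipeline")
print(rep)
```

which also writes every intermediate file in its interchange format (VCF,
PED/MAP, GFF3, FASTA, BED, TSV) plus a consolidated `report.json`; runs are
byte-identical under the same seed.

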