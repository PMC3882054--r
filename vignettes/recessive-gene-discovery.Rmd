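---
title: "Mapping and characterizing a founder-derived recessive allele: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and characterizing a founder-derived recessive allele: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

`autozyg` re-implements, as a tested and reusable workflow, the classic
gene-discovery strategy for a lethal recessive defect segregating in a
closed livestock population: autozygosity mapping from SNP-array genotypes,
two complementary private-variant filtering cascades over whole-genome
callsets, codon-aware annotation of a multi-nucleotide variant (MNV)
cluster, Hardy-Weinberg and segregation statistics, and single-exponential
fitting of two-electrode voltage-clamp (TEVC) gating kinetics.  Every stage
runs against a synthetic-data generator with exact ground truth, so each
claim the workflow makes is checkable.

This vignette is the package's methodological account: the models, the
parameters that matter, the numerical choices, and what the synthetic data
do and do not establish.

## The population model

`build_population()` simulates the demographic situation in which recessive
defects surface in intensively selected herds.  A founder generation
(default 40 animals) contains exactly one heterozygous carrier — a male
used, via the artificial-insemination popular-sire effect, for a large
fraction (default 0.75) of first-generation matings.  Later generations
(default 3) mate within the herd, so the carrier's descendants meet on both
the paternal and the maternal side, and homozygotes for the founder
haplotype appear.  Phenotype is fully penetrant recessive: affected if and
only if homozygous for the causal founder haplotype; affected individuals
are perinatal-lethal and never breed.  The population is re-drawn (bounded
attempts) until at least `target_n_cases` (default 6) affected exist; an
unreachable quota is an explicit error, never a silent shortfall.

Meiosis follows the Haldane model: crossover count per chromosome is
Poisson with mean equal to the map length in Morgans (default 1 cM/Mb over
three 30-Mb chromosomes, i.e. 0.3 Morgans each), crossover positions
uniform on the centimorgan scale, no interference.  Founder-origin labels
travel with every transmitted allele, giving an exact identity-by-descent
(IBD) truth layer; the causal allele is *defined* as descent from the
carrier founder's first haplotype, so carrier state is read off the labels
rather than being a separate mutation model.

Scale was chosen to keep a full simulate–map–prioritize cycle around two
seconds: ~1,000 array markers per chromosome (one per 30 kb, a desk-scale
stand-in for a 50K array), populations of roughly 300–450 individuals, and
a ~1-Mb sequenced region.  These sizes are what the test suite and the
analysis scripts use throughout.

## The toy gene and the planted causal cluster

`make_toy_gene()` builds a five-exon, single-transcript gene whose coding
sequence is a random 2427-bp ORF (809 codons) with fixed landmarks: ATG
start, codon 748 = TCG (Ser), codon 750 = TAC (Tyr), terminal stop.  The
planted causal lesion is a cluster of three substitutions within 7 bp of
one exon — CDS 2244 G>C (third base of codon 748), 2248 T>C and 2250 C>A
(first and third base of codon 750).  Jointly, the codon-750 pair converts
TAC to CAA (Tyr>Gln, "Y750Q") while 2244 is silent (TCG>TCC, "S748").
Annotated one variant at a time, the same data give a spurious nonsense
call (TAC>TAA) — the cluster exists precisely to exercise MNV-aware
annotation, and the test suite asserts that the naive per-variant reading
disagrees.

Coordinates are 1-based inclusive everywhere (VCF convention); BED output
converts to 0-based half-open on disk and the conversion is round-trip
tested.  The gene model is strand-aware: a minus-strand rendition on a
mirrored genome yields byte-identical consequence records, which is a
package invariant.

## Mapping: shared homozygosity and a haplotype-window scan

`shared_homozygosity_segments()` is exact and deterministic: a marker is
*concordant* when every non-missing case genotype is homozygous for the
same allele and at most `max_missing_per_marker` (default 0) cases are
missing; maximal runs of at least `min_markers` (default 10) concordant
markers are reported with boundaries at the outermost concordant markers —
the same convention under which an interval printed as chr25:632,647–
1,781,139 measures (1,781,139 − 632,647)/10^6 = 1.15 Mb.  Correctness is
pinned to a brute-force enumeration oracle on small matrices, and the
interval containing the causal locus is required to contain the truth-IBD
segment.

`haplotype_window_scan()` is a deliberately simplified association scan:
the simulator's haplotypes are phased by construction, so each window of
`window_size` markers reduces every chromosome to a haplotype string, and a
Pearson chi-square on the (haplotype class) × (phenotype) table is
reported with df = classes − 1.  No mixed model and no stratification
correction are attempted: those exist to tame the confounding of real
populations, which the generator does not create.  This simplification is
the package's largest deliberate departure from full-scale practice and is
the reason scan p-values here should never be compared with
genome-wide-significance thresholds from real studies.

Rare haplotypes are pooled into one class before testing.  The pooling
threshold matters more than it looks: with a permissive threshold (pool
only singletons), desk-scale windows carry 20–30 haplotype classes, and the
omnibus chi-square spreads the founder-haplotype signal over ~25 degrees of
freedom, to the point where null windows occasionally beat the causal ones.
The defaults therefore implement a *common-haplotype* scan: windows of 10
markers, haplotypes seen on fewer than 8 chromosomes pooled (roughly the
rarest 4% at the default cohort size).  Under these defaults the
genome-wide minimum p landed inside the truth-IBD interval in 15/15
evaluation seeds, and the scan's type-I error under label permutation stays
at its nominal 0.05 (an acceptance property).  Both knobs remain
configurable.

## Variant prioritization: two cascades and MNV annotation

Cascade A mirrors a discovery filter against controls and a known-variants
catalogue:

1. remove every variant whose alt allele appears in any control (het or
   hom) or whose (chrom, pos, ref, alt) key is catalogued — "found in
   controls or previously reported";
2. keep variants hom-alt in *all* cases (the autozygosity criterion, stated
   explicitly here);
3. keep variants in transcribed regions — read as *exonic* (UTR or CDS),
   not intronic;
4. keep CDS variants;
5. keep amino-acid-changing variants, decided by joint per-codon
   annotation.

The step-1 removal percentage is rounded to the nearest integer (1733 of
2162 prints as 80%).  Counts telescope by construction and the report
carries the retained set at every step.

Cascade B is the segregation filter: survivor iff hom-alt in **all** cases,
het in **all** carriers, and alt-free in **all** non-carriers.  Missing
genotypes are handled asymmetrically, and deliberately so: over cases and
carriers a missing call disqualifies (a missing call cannot certify an
"all" quantifier), while a missing non-carrier call counts as absence with
a warning; both behaviours are configurable.  Survivors are broken down as
intergenic / intronic / coding (coding = CDS; the rare UTR survivor would
count with intergenic), and coding survivors are split synonymous vs
non-synonymous after MNV grouping.

Annotation applies all same-codon substitutions simultaneously, translates
with the standard genetic code (the package's own 64-entry table, checked
exhaustively against an independent reference in the tests), classifies as
synonymous / missense / nonsense / stop-loss, and emits HGVS-like labels
(`c.2248T>C`, `p.Tyr750Gln`, `Y750Q`).  Indels pass through the filters by
(pos, ref, alt) identity but are excluded from codon annotation; the causal
lesion here is a substitution cluster, and frameshift/splice consequence
classes are out of scope.

In the generator, the causal cluster is accompanied by a configurable set
of "linked" variants in perfect co-segregation with the disease haplotype
(default 8 intergenic, 3 intronic, 2 coding-synonymous), emulating the
private neighbourhood that a founder IBD segment drags along.  Linked
variants and the cluster are never catalogued — they are private to the
disease haplotype by construction; background variants enter the catalogue
at `catalogue_fraction`.  Background variants are population-shared
(present in at least one control) with probability `p_in_controls`, or
sporadic (a single het carrier) otherwise.  This is the simplest sharing
structure that exercises both cascades; the generator records per-variant
truth flags so cascade counts are checked against bookkeeping that never
ran through the cascade code.

## Genotype statistics

`hwe_test()` defaults to the Pearson goodness-of-fit chi-square over the
three genotype classes with the allele frequency estimated from the data
(df = 1, no continuity correction).  That choice is itself a finding: on
control counts of 5845 hom-ref / 644 het / 0 hom-alt the Pearson form gives
p = 0.000026 (expected classes 5861.0 / 612.0 / 16.0, statistic 17.7) — a
16-homozygote deficit, the signature of a perinatal-lethal recessive —
whereas the Yates-corrected and exact variants give visibly different
values.  Both alternatives are provided as options; the Monte-Carlo
agreement of the Pearson tail with a multinomial simulation oracle is an
acceptance property.  A cohort where only one allele is observed returns
p = 1 by convention.

`allele_frequency_percent()` keeps the allele/carrier distinction explicit:
644 carriers among 6489 animals is a 9.9% *carrier* frequency but a
100·644/(2·6489) = 4.96% *allele* frequency, rendered "5%".

`check_recessive_segregation()` verifies the full-penetrance recessive
reading against a pedigree: every affected must be hom-alt, every genotyped
parent of an affected must be het, no unaffected may be hom-alt, and any
alt allele in a declared-external cohort (another breed) is flagged.

## TEVC kinetics

`simulate_traces()` produces currents under the standard ClC-7 protocol
(holding −30 mV; 2-s test pulses −80…+80 mV in 20-mV steps; 0.5-s
deactivation pulse at −80 mV; default sampling 1 ms).  During a test pulse
at voltage V,

    I(t) = A(V) · [ f + (1 − f) · (1 − exp(−t/τ_act)) ] + ε,

with instantaneous fraction `f` (default 0.15) and Gaussian noise ε.  The
amplitude `A(V) = g·(V − V_rev) / (1 + exp(−(V − V_mid)/V_slope))` is a
sigmoid-times-driving-force form *invented purely to produce outward
rectification* of the right shape; its parameters are descriptive plumbing,
never fit targets, and the form is mildly non-monotone at strongly negative
voltages (where real ClC-7 inward currents are likewise near zero).  During
the deactivation pulse the current relaxes single-exponentially with
τ_deact toward A(−80), continuous in the gating variable at the step.

`fit_activation()` fits I(t) = I_ss − ΔI·e^(−t/τ) over the first 250 ms of
the +80-mV pulse (window and voltage configurable) — a three-parameter
form including the offset, since an instantaneous current component is
present.  Initialization is by log-linearization of |I − I_ss,est| with
I_ss estimated from the trailing 10% of the window; refinement is
Levenberg-Marquardt.  Non-convergence and non-positive fitted τ are
flagged, never silent; a flat segment returns a zero-amplitude,
non-converged fit.  Noiseless traces from the module's own model class are
recovered to better than 10⁻³ relative error over τ ∈ [20, 2000] ms (a
property test), and fitted τ is invariant under current scaling and time
re-indexing.  One wording note: the source literature for this kind of
analysis sometimes prints such values as "rate constants" in milliseconds;
this package consistently reports them as what they are fitted as —
exponential *time constants*, in ms.

`fit_deactivation()` applies the same machinery to the full 0.5-s
relaxation segment (the fit window is configurable; no shorter window is
prescribed).  `normalize_iv()` reads the steady current as the mean of the
final 10 ms of each pulse (to damp noise; configurable), normalizes per
trace to the +80-mV value — so the curve is exactly 1 there — and averages
across traces with standard errors.  `compare_groups()` is an
equal-variance two-sample Student t-test by default (Welch optional) plus
the fold ratio of group means; two zero-variance groups with equal means
give t = 0, p = 1 rather than an error.

The simulation harness for the group comparison draws per-oocyte true time
constants from the reported group summaries — wild type 341 ± 18 ms
(s.e.m., n = 13), mutant 104 ± 6 ms (s.e.m., n = 18), i.e. per-oocyte s.d.
of s.e.m.·√n — simulates a noisy trace per oocyte (noise 2% of the +80-mV
amplitude), and fits each before testing.  The oocyte counts are reported
inconsistently between text (17 and 13) and figure legend (13 wild-type,
18 mutant) in the source literature for this protocol; the harness uses
13/18 and the discrepancy is noted here rather than resolved.  Under these
conditions the recovered acceleration exceeds 3-fold with t-test
p < 10⁻⁶.

## Determinism and numerical conventions

Every stochastic operation takes an explicit integer seed; the pipeline
derives per-stage streams from one master seed through a fixed affine map
(`derive_seed()`, always below 2³¹).  Identical configuration and seed
give byte-identical reports — an asserted contract, including file output.
Other conventions: genotypes are alt-allele counts {0, 1, 2, NA}; marker
tables are sorted chromosome-then-position on construction; percentage
renderings round half away per R's `round`; chi-square p-values are upper
tails; the exact HWE test enumerates heterozygote counts conditional on
allele counts and sums probabilities ≤ the observed table's (with a 10⁻¹²
slack for ties).

## What passing tests do and do not show

The generator emulates the *structure* of a real study — founder descent,
IBD sharing, private linked variants, catalogue filtering, rectifying
gating — not its noise: there is no genotype-calling error model beyond
symmetric flips, no sequencing coverage model, no population stratification,
no phasing uncertainty (haplotypes are emitted phased), and no demography
beyond the pedigree.  Green tests therefore certify the correctness of the
algorithms under known ground truth and the internal consistency of the
pipeline; they do not certify performance on real array or sequencing data,
where the unmodelled error modes dominate the difficulty.  Cohort-scale
variant counts (how many variants survive each filter step) are properties
of a particular population's data and are checked here only structurally:
counts telescope, partitions sum, and the planted cluster survives.
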