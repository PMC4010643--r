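---
title: "Models and methods behind uroscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind uroscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uroscape)
```

`uroscape` implements the analysis layer that sits downstream of somatic
variant calling and copy-number segmentation in a bladder-cancer
whole-genome study: spectra, driver prioritization, hotspot scanning,
copy-number burden and chromothripsis, amplicon allele profiles, clonal
structure, and burden–clinicopathology associations. This vignette
explains each model, its assumptions, the tunable parameters, and the
design choices made where more than one reasonable construction existed.

## Record-level filters

Three filters precede everything else. Variants require at least 10
covering reads (`depth_filter`, boundary inclusive); variants with a
population allele frequency strictly above 0.05 are removed
(`population_filter`), with *missing* frequencies retained since absence
of population evidence is not evidence of commonness; and exact
(chromosome, position, ref, alt) matches against a blacklist of sites
recurrently miscalled in non-cancer constitutional genomes are removed
(`blacklist_filter`). All three are idempotent, order-preserving, and
mutually commutative, which the test suite asserts on simulated cohorts.
Rearrangement breakpoints are filtered at confidence score ≥ 99
(the caller's scores cap at 99, so "filtered for a score of 99" is read
as a minimum threshold), ≥ 10 supporting read pairs, and — optionally —
at least one anchor inside a catalogued gene.

Upstream caller-internal filters (posterior Phred scores,
genotype-likelihood deltas) act on raw read evidence this package never
sees; they are out of scope here.

## Mutation spectra

Substitutions are collapsed over strand into six classes with pyrimidine
reference representation, so G>A and C>T are one class (C:G>T:A).
`compare_spectra` tests observed six-class counts against reference
proportions with a chi-square goodness-of-fit (expected cells under 5 are
merged into the nearest neighbouring class, reducing the degrees of
freedom) and reports cosine similarity of the proportion vectors as a
scale-free descriptive companion. No specific test is canonical for
signature comparison at six classes; chi-square plus cosine is the
simplest pair consistent with asking "is this spectrum different?". The
96-trinucleotide-context representation and NMF signature extraction are
deliberately out of scope. Region-restricted spectra
(`subset_spectrum`) enable exome-versus-genome comparisons; when such
comparisons are made, variants are pooled across the cohort rather than
averaged per sample (per-sample averaging is a defensible alternative;
pooling was chosen and is stated here so results are interpretable).

## Driver prioritization cascade

The cascade encodes a published filter sequence:

1. Keep every protein-truncating (stop-gain, stop-loss, frameshift) and
   splice-site mutation.
2. Exclude a missense mutation only when **both** predictors call it
   moderate/benign: SIFT > 0.2 **and** PolyPhen2 < 0.8. A missing score
   cannot demonstrate benignity, so missense variants with incomplete
   scores are retained.
3. Synonymous, UTR and intergenic changes never enter the cascade.
4. Drop genes mutated in fewer than two distinct samples
   (`recurrence_filter`); a configurable whitelist lets established
   drivers bypass recurrence so they remain visible for comparison.

The original workflow ends with manual inspection of mutant reads; human
review is not implementable, so the cascade honours an optional
per-variant `low_quality` flag instead, preserving the workflow shape.
The cascade is order-invariant and is tested for exact equivalence
against an independent brute-force predicate scan on randomly annotated
variants. Statistical driver tests with background mutation models
(dN/dS, covariate-adjusted recurrence) are out of scope — the cascade is
a deterministic filter, not a significance test.

## Hotspot scanning

The genome is tiled into non-overlapping 1-Mb windows (sliding windows
are a possible alternative; tiling was chosen for interpretability and
multiplicity control). Each window's total mutation count is tested
against the genome-wide mean density with a one-sided Poisson upper tail,
`P(X ≥ n)` at λ = rate × window width, so shorter terminal windows get a
length-adjusted expectation. Benjamini–Hochberg correction is applied
across windows and windows with q ≤ α (default 0.05) are flagged. Under
a uniform null the family-wise flag rate stays at or below α (the
discrete Poisson p-values are conservative), which the suite verifies on
200 simulated null genomes. Kataegis is not modelled separately (no
inter-mutation-distance changepoint detection); dense local clusters
surface as hotspot windows, a documented simplification.
`annotate_explanations` marks windows whose mean total copy number
exceeds 2.5 (copy-number-explained) and windows within 2 Mb of a
centromere or telomere, where mapping artefacts concentrate.

## Copy-number burden and chromothripsis

A segment is *altered* when its total copy number differs from 2 or it
shows LOH — copy-neutral LOH counts as altered, matching callers that
emit joint copy-number/LOH states. `fraction_genome_altered` requires the
segments to tile the genome and is invariant to state-preserving segment
splits. Chromothripsis is operationalized as ≥ 10 transitions of the
joint (total copy number, LOH) state between adjacent segments on a
single chromosome arm; segments straddling the centromere contribute to
both arms (equivalent to splitting them at the centromere), and the
transition count equals the number of joint-state runs minus one.
Recurrent regions are computed by an exact breakpoint sweep — elementary
intervals between the union of all sample breakpoints, per-interval
distinct-sample counts, and merging of adjacent equal-count intervals —
and verified against per-base counting on small genomes.

## Amplicon allele-fraction profiles

An amplicon region is grown as the maximal contiguous run of segments
with total copy number ≥ 3 containing the anchor gene (3 being the
minimal amplified state). The profile collects germline heterozygote
BAFs and somatic VAFs across the region. The expected heterozygote BAF
at purity *t*, total copy *c*, tracked-allele copy *a* is
`(t·a + (1−t)) / (t·c + 2(1−t))` — 2/3 for a pure 2:1 gain, 7/8 for a
pure 7:1 amplification. The allelic-asymmetry statistic is the mean of
|tumour BAF − 0.5| over heterozygotes: 0 for a balanced region, 0.375
for a pure 7:1 state. Mutation-density excess inside the region is
reported as observed/expected ratios for SNVs and indels against the
rest of the genome, alongside copy-number-adjusted ratios (expectation
scaled by mean copy / 2): an excess surviving adjustment cannot be
attributed to the extra template copies alone.

## Clonal structure

Per-variant cellular prevalence inverts the allele-fraction model:
`f = VAF · (t·c + 2(1−t)) / (t·m)` with multiplicity *m* defaulting to 1
— the conservative choice when the number of mutated copies is unknown;
it is configurable per variant. Estimates are clamped to [0, 1] with
clamping flagged, and copy-number-zero loci are excluded.

Clustering uses a Dirichlet-process binomial mixture: each cluster has a
prevalence φ with a uniform base measure on [0, 1] (discretized on a
201-point grid, which makes the per-variant likelihood precomputable and
the sampler fast and stable); a member variant contributes
`Binomial(depth, φ·s)` where `s = t·m/(t·c + 2(1−t))` is its
prevalence-to-VAF scale. Inference is Gibbs sampling with
grid-integrated new-cluster weights, per-cluster grid resampling of φ,
and concentration resampling under a Gamma(1, 1) prior; defaults are
5,000 sweeps with 1,000 burn-in and a mandatory seed. The reported
partition is the posterior draw minimizing squared distance to the
posterior similarity matrix (Dahl's criterion), and the cluster-count
trace is kept on the fit object as a convergence diagnostic — it is
printed by `summary()`, never silently discarded. A deterministic
fallback (`method = "bins"`: 0.1-wide prevalence bins, adjacent occupied
bins merged) provides a fast non-stochastic path used by default in the
pipeline orchestrator. A beta-binomial emission with genotype-state
priors (as in dedicated clonal-inference packages) is out of scope; the
binomial mixture is sufficient for the burden-association analyses this
package targets, and published per-tumour cluster counts are treated as
fixture inputs for association tests, not as recomputation targets,
because they depend on unrecoverable settings of the original tool.
`sensitivity_over_dna_index` refits the clustering under alternative DNA
index (ploidy-model) candidates and reports whether cluster counts agree
within ±1, flagging clamp-dominated (near-zero purity) candidates as
unreliable.

## Association statistics

Three rank statistics are implemented to match the exact variants that
reproduce published cohort p-values:

* `spearman_rho`: Pearson correlation of midranks with a two-sided
  t-approximation p on n − 2 df, pairwise-complete.
* `wilcoxon_ranksum`: normal approximation with tie-corrected variance
  and **no** continuity correction. This is the unique standard variant
  consistent with both the tie-free and the tied published p-values
  (0.0047 for mutation counts with complete group separation; 0.0046
  for the copy-number fraction where two samples tie at 14%), so it is
  the default; the suite cross-checks it against
  `stats::wilcox.test(exact = FALSE, correct = FALSE)`.
* `kruskal_wallis`: tie-corrected H via `stats::kruskal.test`; with two
  groups H equals the squared rank-sum z, asserted as a property test.

For stage tests, pT1 and pT2 are pooled against pTa, following the
observation that no burden measure separates pT1 from pT2 at these
sample sizes. Burden is measured as the genomic SNV count (GSM); raw
p-values are reported by default (no multiplicity correction), with a
Benjamini–Hochberg option. `association_screen` routes each (burden,
factor) pair to the right test and reports pairs with fewer than three
complete cases or a single factor level as untestable rows rather than
dropping them.

One published value does not reproduce from the printed table: the
clonality-versus-copy-number-fraction correlation computes to
ρ = 0.59 (p = 0.026) here against a published 0.61 (p = 0.021); the
discrepancy is not resolvable from the printed data and the computed
value is reported as-is. The clonality-versus-stage p-value computes to
0.0060, consistent with the published exact value (one printed rendition
drops a zero).

## The synthetic cohort generator

`generate_cohort` emulates the statistical structure of a
stage-stratified whole-genome discovery cohort:

* **Genome**: 22 autosomes scaled to 1/20 of human reference lengths
  (~144 Mb total) with proportionally placed centromeres and a gene
  catalog anchoring known bladder-cancer genes at scaled native
  positions. Every downstream statistic is scale-free (densities,
  proportions, rank tests), so the scale factor is a runtime
  convenience, configurable back to full length.
* **Burden**: per-sample SNV counts are Poisson around stage-group means
  (defaults 35,000 for pTa and 115,000 for invasive groups, the
  published per-tumour scale); indel counts are Poisson with mean
  0.22 × the sample's SNV count, which reproduces the published
  indel:SNV ratio and makes the two counts strongly correlated, as
  observed. (The published text quotes a slightly different burden range
  than the summary table; the generator targets the table's scale.)
* **Spectrum**: classes drawn from a six-class multinomial, default
  (0.33, 0.15, 0.17, 0.20, 0.09, 0.06) — C:G>T:A most common, then
  T:A>C:G and C:G>G:C.
* **Reads**: per-site depth Poisson(80) (the published median depth);
  alt reads Binomial(depth, expected VAF) with
  `VAF = t·f·m / (t·c + 2(1−t))`.
* **Clonal structure**: non-invasive samples are monoclonal (prevalence
  1.0); invasive samples carry a subclone at prevalence 0.4. True clone
  labels are emitted for recovery tests.
* **Copy number**: each chromosome is split at uniform breakpoints
  (1 + Poisson(2) segments) with per-segment states drawn at rates
  gain 0.15, loss 0.15, copy-neutral LOH 0.05, homozygous deletion 0.01;
  segments tile each chromosome exactly. Focal amplicons
  (`inject_amplicon`) and chromothripsis arms
  (`inject_chromothripsis`) are injected on top. Germline heterozygous
  SNPs are seeded (default 1 per 100 kb) solely for BAF profiling.

What the generator does **not** emulate: sequencing error and mapping
artefacts, trinucleotide context, mutation clustering (kataegis),
stage-dependent copy-number rates, germline variation beyond het
seeding, and read-level data (FASTQ). Passing tests on synthetic cohorts
therefore demonstrate the correctness of the downstream computations
under the stated statistical model — not robustness to caller artefacts
in real data.

## Numerical and reproducibility choices

Coordinates are 1-based inclusive on disk (VCF, segment TSVs) and
converted internally where half-open arithmetic is simpler; a variant at
position 1,000,001 falls in the second 1-Mb window. Every stochastic
entry point takes a mandatory seed and fixed seeds give byte-identical
output; the default gene catalog draws its filler placement from a
private RNG stream so constructing a genome never perturbs a caller's
seed. Degenerate inputs are explicit: zero SNVs give a flagged empty
spectrum, zero variants give a clean no-hotspot return, constant vectors
are an error for Spearman, identical groups give p = 1 for the rank-sum
test, an anchor gene without an amplified segment gives an empty profile
carrying its reason, and segment tables with gaps fail with the gap
coordinates.

Test and example problem sizes (hundreds to a few thousand variants per
sample, 1/20-scale genome, 200-genome null batteries, 600–5,000 Gibbs
sweeps) were chosen so the full suite runs in about a minute while
keeping every statistical margin wide; the acceptance script uses a
1/10-scale burden cohort for its spectrum summaries, which is stated
here because spectra and ratios are scale-free.

## Known limitations

* The driver cascade has no background mutation model; it prioritizes,
  it does not test.
* The hotspot scan's Poisson null ignores regional mutability
  covariates (replication timing, chromatin), so its flags are
  descriptive screens.
* The clonal model fixes multiplicity at 1 by default and ignores
  subclonal copy number; prevalences at amplified loci are accordingly
  approximate.
* Published per-tumour cluster counts (up to 36) are not recomputation
  targets — they depend on the original tool's settings — and are used
  as fixture inputs to the association analyses instead.
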