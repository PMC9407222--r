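---
title: "comparascan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{comparascan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

comparascan implements the comparative population-genomic scan layer used in
multi-species resequencing studies of wild canids and similar panels: given a
joint multi-sample VCF, a species panel, a genome layout and a transcript
annotation, it computes per-sample heterozygosity tracks, runs of
homozygosity (ROH) with length-class summaries, an enrichment scan for
lineage-private alleles in regulatory flanking windows of transcripts,
lineage-unique high-impact variant reports, and a per-sample genetic-load
tally of homozygous-derived damaging genotypes. A genotype simulator with
exact truth files makes every stage verifiable by parameter recovery at desk
scale. This vignette records the statistical model behind each stage, the
parameters that matter, and the design decisions taken where the design was
genuinely open.

## Data model

The central container is the `VariantPanel`: a sorted `GRanges` of variant
positions (multiallelic sites kept unsplit) carrying REF/ALT alleles and
optional per-site annotations - ancestral allele, impact category
(HIGH/MODERATE/LOW/MODIFIER), a deleterious flag, and a gene id - plus two
integer allele-index matrices holding each sample's unordered diploid
genotype (`NA` = missing, never imputed). Annotations are consumed from
configurable INFO keys (`AA`, `IMPACT`, `DEL`, `GENE` by default); the
package never computes variant consequences itself.

Coordinate conventions: VCF and GFF3 are 1-based inclusive on disk; all
in-memory intervals are `GRanges` (1-based closed), the interval container
of the Bioconductor ecosystem, whose overlap machinery replaces hand-rolled
interval arithmetic; BED and BEDGRAPH outputs are 0-based half-open as those
formats require. A genotype is heterozygous iff its two allele indices
differ, regardless of which alleles are involved - heterozygosity here is a
per-genotype property, not a per-allele one.

## Sliding-window and per-site heterozygosity

`tileWindows(layout, size, step)` places windows starting every `step` bp
while the start lies inside the chromosome, truncating the trailing windows
at the chromosome end, so every base is covered whenever `step <= size`. The
chromosome-painting configuration used for genome-wide diversity figures is
100-kb windows with a 10-kb step.

`windowHeterozygosity()` counts heterozygous genotypes per window. The
denominator question - raw window length versus callable sites - is left to
the user because joint callability is not always available: the default
denominator is the full window length (reproducible from a VCF alone), and
an optional BED callability mask shrinks it to the masked window length
minus the window's missing genotypes. `perSiteHeterozygosity()` divides the
genome-wide heterozygote count by a callable length (default: total genome
length) and reports het/kb, the scale on which per-site heterozygosity of
wild canids spans roughly 0.3-2 het/kb. With a non-overlapping tiling the
sum of window counts equals the genome-wide count exactly; with `step <
size` an interior site is counted in exactly `size/step` windows.
Chromosomes can be excluded from summaries (e.g. the X from "autosomal"
heterozygosity) via the pipeline's `excluded_chromosomes` list.

## Runs of homozygosity

`callROH()` re-implements the scanning-window heuristic popularized by PLINK
`--homozyg`, with every parameter explicit (`rohParams()`): a window of
`scanSnpCount = 50` consecutive sites is a *hit* iff it contains at most
`maxHetInScan = 1` heterozygous and `maxMissingInScan = 5` missing genotypes;
a site qualifies when at least `hitThreshold = 5%` of the windows covering it
are hits; maximal runs of consecutive qualifying sites - split where the
inter-site gap exceeds `maxGap = 1 Mb` - are reported when they hold at least
`minSnps = 100` sites and span at least `minLength = 100 kb`. Segment bounds
are site-defined (first to last site of the run), which makes the exhaustive
brute-force oracle in the test suite unambiguous. These defaults mirror
common practice and are all overridable; they are declared, not inferred
from any published SI table.

Segments are classified as short (0.1-1 Mb), medium (1-10 Mb) or long
(>= 10 Mb), with half-open lower bounds so a segment of exactly 1 Mb (10 Mb)
is medium (long). `classifyAndSummarize()` reports per-class counts, summed
lengths and genome fractions plus F_ROH (total ROH length over genome
length), the genomic inbreeding coefficient; sub-0.1-Mb segments are
discarded into a tally. Long ROH indicate recent inbreeding, short ROH older
coancestry, so the three-class summary is the standard way small or
bottlenecked populations (island foxes, zoo founders) are contrasted with
large outbred ones.

One behavior worth knowing: with `maxHetInScan = 1`, runs extend a few sites
past a true autozygous tract boundary (until scanning windows accumulate a
second heterozygote), so recovered boundaries overshoot by roughly the local
spacing of the carrier's heterozygous sites. Recovery is therefore scored by
interval Jaccard overlap (>= 0.95 in the acceptance scenario) rather than by
exact endpoints.

## Private-allele enrichment in regulatory flanking windows

For each gene (longest isoform only, selected by `longestIsoforms()`),
`buildFlankWindows()` takes the `flank = 1000` bp immediately upstream of the
transcript start and immediately downstream of the transcript end - a
promoter/terminator proxy - clipped at chromosome edges; a fully clipped
gene keeps a zero-width window so it still appears in reports (with zero
counts and P = 1). The two windows of a gene never overlap the body by
construction; `reduce()` merging is retained for degenerate edge cases.

A site is *private* to a focal species iff some alternate allele - restricted
to derived alleles when the ancestral allele is known - is carried by at
least one focal sample and by zero called samples of every other species;
sites with no called non-focal genotype are never private. Polarity matters:
when `AA` is present, a reference allele carried only by the focal species
also counts (the reference genome is itself an ingroup and is never assumed
ancestral).

`scanGenes()` reports, per gene: the focal private-allele count in its
flanks, the mean per-species count of sites variable *within* each
background species over the same windows (the "average number of variable
sites across the remaining species"; the within-species reading of that
phrase is implemented and flagged here), their ratio with a pseudocount-1
floor on the denominator (rank-preserving among nonzero denominators, no
division by zero), and a one-sided P value for private-allele excess.

### The null model

Three nulls are available. The default analytic null is **Poisson**: under
spatial homogeneity the number of private alleles in a gene's flanks has
expectation (genome-wide focal private rate per bp) x (flank length). A
**binomial** null (flank-length trials at the per-bp rate) is provided for
comparison, and an **empirical permutation** null re-draws `nPerm = 10000`
windows of the gene's total flank length uniformly from the genome and uses
the empirical upper tail. The Poisson default was chosen by a model-level
calibration analysis: for a point process of private sites, window counts
are Poisson, and a binomial null understates their variance by the factor
(1 - rate), which measurably mis-calibrates the test once the per-window
expectation is large; the Poisson null is exact in that regime and
indistinguishable from the binomial at low rates.

Because counts are discrete, the tail convention matters. `pType = "midp"`
(default) reports the mid-P value `P(X > x) + P(X = x)/2`, the standard
calibration-preserving yet deterministic choice, used for all significance
calls. `"exact"` gives the conservative `P(X >= x)` (under which a gene with
zero private alleles has P exactly 1). `"randomized"` gives the randomized
PIT `P(X > x) + U P(X = x)`, exactly Uniform(0,1) when the null model
matches the data-generating process; it exists for calibration diagnostics -
no deterministic transform of a discrete count can pass a tight uniformity
test, while the PIT turns the uniformity check into a genuine test of the
null model itself - and is not meant for reporting.

Raw P values with the conventional `alpha = 0.01` threshold are the default
(no multiple-testing correction), matching how such scans are conventionally
reported; Benjamini-Hochberg FDR is available via `adjust = "BH"`.

`compareGeneSet()` computes, for a named gene set (e.g. genes of a skeletal
pathway), each species' proportion of private alleles among all variable
sites in the set's flanking windows, the quantity used to contrast focal
lineages against the remaining species. An optional user-supplied BED of
conserved intervals can be intersected upstream when a conservation filter
is wanted; the package does not define one.

## High-impact variants and damaging load

`uniqueHighImpact()` filters to sites annotated HIGH that are private to the
focal species and groups them by gene; both the gene tally and the variant
tally are reported, since either may be the quantity of interest.
`damagingLoad()` counts, over sites flagged deleterious and polarized by an
ancestral allele, genotypes homozygous for a derived allele (and,
separately, heterozygous carriers). Deleterious sites without an ancestral
allele are excluded and tallied rather than silently dropped. Both
operations are checked against exhaustive per-site re-scans in the tests.

## The genotype simulator

`simulatePanel()` generates the statistical structure the scans assume,
with exact bookkeeping:

* **Heterozygosity.** Per species, polymorphic sites are a homogeneous point
  process with all samples of the species heterozygous at the species'
  sites, so each sample's expected het/bp equals the configured `het_rate`.
  Every such allele is also given to homozygous-alternate "sharer" samples
  in up to two other species - homozygous so the sharers' heterozygosity is
  untouched - which guarantees background variants can never masquerade as
  private alleles.
* **Autozygosity.** Implanted tracts are literal forced
  homozygous-reference intervals for the carrier, so tract boundaries are
  known exactly for recovery scoring (rather than pedigree-derived IBD with
  fuzzy ends).
* **Private alleles.** Injected as derived singletons: one random focal
  sample carries the alternate allele (heterozygous or homozygous by coin
  flip), everyone else is ancestral-homozygous, and the ancestral allele is
  recorded, so privacy holds by construction. The background rate applies
  genome-wide; inside the flanking windows of `targetGenes` the rate is
  multiplied by `enrichmentFactor` (or set absolutely via
  `targetPrivateRate`, which also expresses the degenerate all-in-flanks
  design with zero background). Injected alleles are flagged deleterious
  with probability `damagingFraction`; flagged alleles are homozygous in
  their carrier with probability `min(1, 0.5 * homDamagingBias[carrier])`,
  so a bias of 2 doubles a sample's expected homozygous damaging load.
* **Collisions.** Sites are drawn independently per process; duplicate
  positions are resolved by keeping the first-drawn site. At realistic rates
  the loss is negligible; at the deliberately extreme rate of the null
  calibration scenario it is a few percent, and it is self-consistent
  because the scan estimates its rate from the emitted panel, not from the
  configuration.
* **Truth.** `SimTruth` counts (per-species private sites, per-sample
  damaging homozygotes) are recomputed from the emitted genotype matrix at
  write time, never assumed from the configuration.
* **Determinism.** One seed drives everything through a single RNG stream;
  identical seed and configuration give byte-identical VCF, GFF3 and truth
  JSON.

Sites are independent - there is no linkage, recombination map, mutation
spectrum or demographic site-frequency structure. That is sufficient and
deliberate: every statistic in the package is site-wise or window-wise, so
independent sites keep the recovery oracles exact. It also bounds what
passing tests show about real data: the simulator validates the
*computations* (counting, windowing, run detection, calibration of the
homogeneous null), not robustness to LD, rate heterogeneity along the
genome, callability artifacts or annotation error. On real panels, rate
heterogeneity makes the homogeneous analytic nulls anticonservative in
rate-elevated regions; the permutation null is the robust alternative and
agreement between the two is itself a useful diagnostic.

## Verification scenarios and problem sizes

The reference scenarios (`?studyConfigs`) fix the study conditions for the
acceptance checks; sizes were chosen once, for statistical resolution:

* Heterozygosity recovery: rates 3e-4, 1e-3, 2e-3 /bp on 10 Mb, so each
  99% Poisson interval is +-2.6 sqrt(lambda) around 3,000-20,000 sites and a
  2-fold rate separation cannot rank-invert.
* ROH recovery: tracts of 0.3, 3 and 30 Mb (one per length class) in ten
  inbred samples at 1 het/kb site density - several hundred to tens of
  thousands of sites per tract, enough that Jaccard >= 0.95 is expected with
  the documented boundary overshoot of a few kb.
* Null calibration: 2,000 genes with ~100 expected privates per flank pair
  (private rate 0.05/bp - a calibration stress configuration, not a
  biological regime), making the discrete null effectively continuous so
  the PIT-uniformity and alpha-band checks have teeth.
* Power: background 2 privates per flank pair, 10-fold enrichment at 20
  target genes; thresholds for recall and false positives were precomputed
  from 5,000 model-level replicates (`tools/power-oracle.R`) and frozen in
  a test fixture.
* Load bias: `homDamagingBias = 2` for one of four focal samples, ~75 vs
  ~37 expected homozygous damaging genotypes, checked over ten replicate
  seeds.

## Numerical and degenerate-input choices

Longest-isoform ties break by transcript id; scan output sorts by P value
then gene id; permutation P values use the (1 + b)/(n + 1) convention; the
ratio pseudocount is 1; empty gene sets and unknown samples/species are hard
errors; a chromosome with fewer sites than the ROH scanning window is
skipped with a warning rather than an error; unsorted VCFs and panel samples
missing from the VCF header abort with the offending record or sample named.
Seeds for pipeline substreams derive from the single run seed and stay below
2^31.

## Limitations

Beyond the simulator's scope (above): the ROH caller is the scanning-window
heuristic, not a likelihood HMM; genotype calling, VEP/SIFT annotation,
liftover and conservation scoring are upstream of this package; the
flanking-window scan treats indels and multiallelic sites like SNVs (they
are retained, flagged by their alleles, and can be filtered by the user);
and the "variable sites across the remaining species" quantity uses the
within-species reading, as noted.
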