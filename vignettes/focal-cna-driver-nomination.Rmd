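---
title: "Nominating driver genes from focal copy-number aberrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating driver genes from focal copy-number aberrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalCNA)
```

## The problem

Osteosarcoma genomes are chaotic: broad gains and losses cover so much of
the genome that almost every gene is recurrently aberrant, and recurrence
alone cannot separate driver genes from passengers. Focal copy-number
aberrations — somatic events of 3 Mb and smaller — are a sharper signal:
under a selection argument, a small recurrent event is likely to be
maintained because of a specific gene inside it. focalCNA implements the
full nomination pipeline built on that idea:

1. per-sample normalization, segmentation and gain/loss calling of
   SNP-array log2ratio profiles;
2. removal of germline copy-number variants (CNVs) in two steps — catalog
   overlap, then recurrent bidirectionality;
3. reduction of each recurrent focal locus to its high-frequency region
   (HFR), the smallest genomic overlap of the contributing aberrations;
4. mapping genes onto HFRs;
5. integration with expression: a gene in a focal loss must be
   underexpressed (fold change at or below 0.75 against a reference
   profile), a gene in a focal gain overexpressed (at or above 1.5), in at
   least 35% of tumors, to be nominated;
6. confirmation of nominees in an independent expression set, and
   supporting statistics (census-gene enrichment, cohort-frequency
   comparison).

A synthetic cohort generator with a recorded truth set makes every stage
testable end to end without array downloads.

## Segmentation and calling

Profiles are median-normalized, then segmented by circular binary
segmentation: on each chromosome (viewed as a circle) the arc that
maximizes the two-sample mean-shift statistic

$$T(i,j) = \frac{\left|S_j - S_i - \tfrac{l}{n} S_n\right|}
                {\sqrt{l\,(n-l)/n}}, \qquad l = j - i,$$

with $S$ the prefix sums, is tested by a seeded permutation test; accepted
splits recurse, and adjacent segments whose means differ by less than a
merge tolerance (default 0.05) are re-joined. The $O(n^2)$ arc scan runs in
C++. The permutation test uses sequential early stopping: it stops as soon
as the p-value can no longer fall below `alpha` (after
$\lfloor \alpha\,m \rfloor + 1$ exceedances, a Besag–Clifford stop) or as
soon as significance is already decided (no exceedance after
$\lceil 1/\alpha \rceil$ draws, giving $p = 1/(m+1) < \alpha$). This leaves
the accept/reject decision at level `alpha` unchanged while cutting the
cost of clear cases by an order of magnitude.

Two numerical consequences are worth knowing. First, permutation p-values
are discrete: a tied run of $k$ probes among $n$ cannot reach a p-value
below roughly $n/\binom{n}{k}$, so very short segments in noiseless data
are undetectable at small `alpha` regardless of effect size — the test
suite's exhaustive-oracle comparisons therefore use change-points at least
6 probes apart. Second, segments are reported on the minimal probe support:
a segment spans from its first probe position to its last probe position
plus one (0-based half-open), so event sizes are resolved to the probe
grid.

After segmentation each sample is mode-normalized: the probe-weighted
kernel-density peak of the segment means (Gaussian kernel, bandwidth 0.1
log2ratio units) is taken as the diploid level and subtracted; ties between
equal peaks resolve toward zero. The peak is polished by Newton iteration
on the exact kernel mixture, which makes a second normalization pass the
identity to machine precision. Calling then uses symmetric inclusive
thresholds (default ±0.2): this is a deliberate three-state surrogate for
mixture-model callers — published tables in this field report only
gain/neutral/loss, and a threshold rule is reproducible without fitted
mixture parameters. The thresholds are configuration-exposed.

## Germline-CNV filtering and HFRs

Aberrations are maximal runs of same-state segments. The focal flag is an
inclusive 3 Mb limit. Two rules remove germline variation:

* **Catalog rule** — a focal aberration is removed when the union of
  catalog intervals covers at least half of it. A bare ≥1 bp criterion
  would delete aberrations sharing a single boundary probe with a common
  CNV, so a coverage fraction (default 0.5, configurable) is used.
* **Bidirectionality rule** — focal aberrations of both directions are
  pooled into single-linkage overlap clusters (≥1 bp); a cluster showing
  recurrent (≥2 samples) gains *and* recurrent losses is removed in full.
  Inherited polymorphic loci produce both deletions and duplications in a
  cohort; selected somatic events do not.

Remaining focal aberrations are clustered per direction, and each cluster's
HFR is the leftmost maximal contiguous run attaining the cluster's maximum
per-base count of distinct focally aberrant samples. For mutually
overlapping aberrations this is exactly their intersection ("smallest
genomic overlap"); for non-transitive chains the maximal-depth run is the
natural generalization, with the leftmost run taken on ties. The focal
count is that maximum depth; the total count adds every sample whose
same-direction aberration — of any size — fully contains the HFR. The
filter ledger records observed/removed/retained counts with the
subtraction identity enforced; the pipeline counts recurrent focal
aberrations (members of ≥2-distinct-sample same-direction clusters) as its
ledger unit, since published ledgers of this kind mix "changes" and
"locations".

## Expression integration

Expression intensities are put on log2ratio scale against the mean
reference profile, corrected per sample for intensity-dependent trend by
local regression of the log2ratio on average log2 intensity (loess, span
0.3), and quantile-normalized across samples (both via limma). Fold
changes are linear-scale ratios; when several probes map to one gene, the
probe with the highest mean intensity across all samples is used, and
genes without a usable probe are carried as explicit no-information rows.
The pipeline computes fold changes after normalization; the plain
ratio-of-intensities route is also exposed because the published
description is ambiguous about the order.

Flagging is inclusive (≤0.75 / ≥1.5) by default, with a strictness switch,
because the primary text states inclusive bounds while a figure legend
prints strict ones. The 35% frequency-of-involvement rule uses all tumors
in the expression set as denominator (not only copy-number carriers) and is
inclusive; frequencies are compared unrounded and displayed as rounded
percentages. Validation in an independent set recomputes the frequency with
the same operations; a nominee is confirmed at ≥35%, rejected below, and
marked no-information when the validation platform lacks a probe. One
documented discrepancy in the source material (84 vs 85 genes with
expression information) is surfaced here: the package follows the Results
figure of 85.

## Statistics

Census enrichment uses the analytic upper hypergeometric tail
$P(X \ge k)$ with an optional seeded permutation cross-check ((+1)/(+1)
corrected); the universe is the supplied gene catalog, since the original
enrichment procedure is described only by citation. Cohort comparison
remaps two call sets onto the intersection bins of their tilings,
propagates states, scores them ordinally (loss −1, neutral 0, gain +1) and
applies a rank-sum test with ties per bin (normal approximation, or label
permutation), with Benjamini–Hochberg q-values. On heavily tied three-level
data the rank-sum test is mildly conservative; in null simulations
(20 vs 20 samples, 200 bins) the fraction of bins at p < 0.05 averages
about 0.05 with per-seed spread of roughly 0.01–0.07.

## The synthetic cohort generator

The generator emulates the study conditions at reduced scale. Defaults:

* **Genome** — 6 chromosomes of 50 Mb, probes every 150 kb (~2,000
  probes), 240 non-overlapping genes of 20–200 kb, 12 polymorphic CNV loci
  of which 60% are in the catalog. This grid is a desk-scale stand-in for
  a 370k-SNP array: all downstream rules depend on probe counts and
  bp sizes, both of which are preserved in proportion, and the reduced
  size keeps twenty seeded end-to-end runs within minutes.
* **Copy-number cohort** — 26 samples. Planted per sample: broad arm-level
  events (Poisson mean 1.5, amplitude ±0.4 — attenuated relative to the
  single-copy ideal, as arm events in real tumors often are subclonal);
  recurrent focal events around 5 loss-driver and 3 gain-driver genes
  (carrier probability 0.65, mid-range of reported discovery frequencies
  of involvement; amplitudes −1.0/+0.58, the ideal diploid single-copy
  log2ratios, since no effect sizes are published); non-recurrent focal
  passengers (Poisson mean 0.5); and germline CNV events at polymorphic
  loci (carrier probability 0.5, as for common polymorphisms, with
  carriers split roughly evenly between deletion and duplication alleles).
  Probe noise is Gaussian with sd 0.15, typical of SNP-array log2ratios.
* **Placement geometry** — planted driver and germline loci keep margins
  from chromosome ends and midpoints (where broad events break) and from
  each other, and passengers avoid planted loci. On a full-size genome
  these collisions are rare by area; on a 10×-scaled genome they would
  dominate, so the generator excludes them so that each planted event
  class exercises exactly one filter and the truth stays recoverable.
  Stress configurations can re-enable collisions by raising the rates.
* **Expression** — 31 discovery tumors against 1 reference sample (84
  tumors against 3 references for validation), log-normal baseline
  intensities (meanlog log 500, sdlog 1), multiplicative log-normal noise
  with sdlog 0.1 (bead-averaged array intensities have low technical
  variation), driver effect multipliers 0.5/2.0, and a 10% chance for a
  non-driver gene to lack a probe (planted drivers always keep one so that
  recovery is measurable).

What the generator does *not* emulate: B-allele frequencies, tumor purity
and ploidy mixtures, probe-specific affinity, spatial waviness, RNA-seq
counts, or correlated passenger landscapes. Passing recovery tests
therefore demonstrates that the pipeline's logic is correct under its own
model assumptions — not that the thresholds are optimal for any particular
real dataset.

With a single reference sample, each gene's reference noise draw shifts
all of that gene's fold changes together; an upper-tail draw can push a
true driver below the frequency rule in an occasional seed. This is a
faithful property of the single-reference design, and it is why the
planted-driver recovery check is stated over 20 seeds with a ≥18/20
criterion rather than per-seed.

## Problem sizes used in the checks

The test suite and acceptance script run: 20 end-to-end seeded cohorts
(26 samples × ~2,000 probes, 200 permutations per split test), 100 noisy
step-recovery replicates at 200 probes, exhaustive oracle comparisons at
≤50 probes, and pooled null calibration over 10 × 200 bins. These sizes
are the package's chosen trade-off between statistical resolution of the
checks and quick, repeatable runs.

## Known limitations

* Three-state calling only: amplifications and homozygous deletions are
  not distinguished from single-copy events.
* The HFR for non-transitively overlapping chains is a convention
  (maximal-depth run, leftmost tie-break); other conventions are
  defensible.
* The bidirectionality rule removes whole overlap clusters; a true driver
  locus that genuinely overlaps a polymorphic locus would be discarded
  with it.
* No purity/ploidy correction: heavily contaminated samples would need
  lower calling thresholds.
* The rank-sum cohort comparison is per-bin; region-level multiple-testing
  control is out of scope.
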