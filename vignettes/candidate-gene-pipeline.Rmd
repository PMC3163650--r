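---
title: "Methods: candidate-gene discovery for divergently bred mouse lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene discovery for divergently bred mouse lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divergene)
library(dplyr)
```

## The problem

Two mouse lines selectively bred for high (HAB) and low (LAB)
anxiety-related behaviour differ in a polygenic trait. A route to candidate
genes is to profile transcriptomes of the limbic brain regions that shape
the phenotype — cingulate cortex (Cg), nucleus accumbens (NAc),
paraventricular (PVN) and supraoptic (SON) hypothalamic nuclei, basolateral
(BLA) and central (CeA) amygdala, dentate gyrus (DG) — contrast the lines
region by region, keep genes regulated consistently across regions, confirm
them by qPCR, and then sequence confirmed loci for allelic differences that
could explain the expression change. `divergene` implements that analysis
chain as reusable, tested functions, together with a synthetic-data module
that generates every input with known ground truth.

## Two-colour arrays: the measurement model and its normalization

A two-colour hybridization co-hybridizes the two line samples labelled with
Cy5 (intensity `R`) and Cy3 (`G`) on one slide. Analysis operates on the
MA plane, `M = log2 R - log2 G`, `A = log2 sqrt(R G)`. Normalization
proceeds in the order global → loess → sub-array:

1. **Global median** (`normalize_global()`): subtract the per-array median
   of usable M; justified by the assumption that the channels correlate and
   most genes are unregulated. Afterwards the usable-M median is 0 to
   floating precision.
2. **Intensity-dependent loess** (`normalize_loess()`): dye incorporation
   bias varies with spot brightness, bending the MA cloud. A locally
   weighted linear regression of M on A (tricube weights, robustness
   iterations, neighbourhood containing `span = 0.40` of the spots — the
   conventional definition of the cited smoother; the C implementation in
   `stats::lowess()` does the fitting) is subtracted. The fitted curve is
   stored on a 101-point A-grid for inspection (`plot_ma()` overlays it).
3. **Sub-array balancing** (`normalize_subarray()`): per print-block median
   subtraction, removing offsets from uneven probe deposition or locally
   unbalanced fluorescence. The step is idempotent. We interpret the
   narrative "several subsequent normalization steps" as this single
   within-slide balancing operation; anything beyond it is out of scope.

Spots with a non-positive intensity in either channel have no log ratio;
they are flagged, carried as missing, and excluded from every median and
fit. Medians are midpoint medians throughout.

**Dye-swap orientation.** Half of the slides carry HAB on Cy5, half the
reverse. `orient_and_stack()` flips the sign of M on the swapped slides so
every column of the stacked probe-by-array table measures log2(HAB/LAB).

**A numerical symmetry worth stating.** The pipeline is exactly
equivariant under a global channel swap: swapping `R` and `G` everywhere
and flipping the orientation labels yields a bit-identical stacked matrix.
Two implementation choices buy this: M is computed as `log2 R - log2 G`
(negation then commutes exactly with the swap, unlike `log2(R/G)`), and
the loess curve is antisymmetrized — the smoother is fitted to M and to
−M and the two fits averaged with opposite signs, making the fitted curve
exactly odd under the swap while coinciding statistically with a single
fit.

## Permutation differential expression (maxT)

Per probe, across the replicate arrays of one region, `probe_stats()`
computes the mean oriented log ratio and the one-sample statistic
`t = mean / (sd / sqrt(n))`. The source text does not name its per-probe
statistic; we use this one-sample location statistic because the dye-swap
design provides the exact exchangeability that justifies its permutation
null: under no line difference, each array's oriented M vector is
symmetric about zero, so the joint null is generated by independent sign
flips of whole array columns.

`permutation_adjust()` computes Westfall–Young **step-down maxT** adjusted
p-values: probes are ordered by observed |t|, and for each sign assignment
the successive maxima of null |t| from the least significant probe upwards
are compared against the observed values. Adjusted p-values use the
add-one convention `p = (1 + b)/(1 + B)`, cannot be zero, and are
monotone-enforced in the rank of |t|. When `2^n_arrays <= n_perm` the sign
orbit is enumerated completely (1,024 assignments for ten arrays);
otherwise `B` random sign vectors are drawn from a seeded stream. The
counting loop is compiled (Rcpp), and the observed |t| is computed with
bitwise the same arithmetic as the permuted statistics so that the
identity assignment always reproduces it exactly — without this, last-ulp
differences between two mathematically equal variance formulas can silently
drop the identity flip from the count, an anti-conservative off-by-one.
Probes with zero spread get an infinite statistic, ranked above all finite
ones; probes with fewer than two observations are dropped with a warning.

The family-wise guarantee is checked two ways in the test suite: exact
agreement with a plain-R brute-force enumeration oracle, and a negative
control in which null self-hybridization experiments (the same sample
against itself, dye bias and noise still applied) are pushed through the
whole pipeline — mirroring the wet-lab control in which self-hybridized
dye-swapped samples returned no significant probe. Note that this control
sits exactly at the nominal boundary: an exact procedure at family-wise
level 0.05 is *expected* to produce a discovery in about 5% of null runs,
so "zero discoveries in at least 95 of 100 runs" is a coin-flip-adjacent
event for any correct implementation, not a margin.

## Single-channel path: quantile normalization and moderated t

Bead-array style single-channel matrices are log2-transformed and mapped
to the mean quantile profile (`normalize_singlechannel()`, delegated to
`limma::normalizeQuantiles`); the spline-based normalization named in the
source is package-specific and not reproducible from its text, and
quantile normalization is the standard rank-preserving stand-in — after
it, column quantiles agree exactly, so planted per-sample scale factors
vanish.

`moderated_t()` ranks probes with an empirical-Bayes moderated
t-statistic: per-probe pooled variances are shrunk towards a prior,
`s~2 = (d0 s0^2 + d s^2)/(d0 + d)`, and the group contrast is tested on
`d0 + d` degrees of freedom. The hyperparameters `d0`, `s0^2` come from
closed-form moment matching of a scaled-F model on the log residual
variances (mean and variance of `log s^2` against digamma/trigamma
moments; the trigamma inverse is a Newton iteration). The limits behave as
expected — `d0 = 0` recovers the ordinary t-test, `d0 = Inf` a
common-variance z-like statistic — and the fit agrees with
`limma::squeezeVar`/`eBayes` as an independent cross-check in the tests.
A degenerate variance fit falls back to the ordinary t-test with a
message.

## Cross-region candidate selection

Percent regulation of an oriented fold ratio `r = 2^mean_M` is defined as
`100 * (max(r, 1/r) - 1)` — the magnitude ratio between the higher- and
lower-expressing line, so a six-fold difference is 500% regulation in
either direction. The source never defines "X% greater regulation"
algebraically; the ratio scale (not log scale) matches its use of
multi-hundred-percent figures for multi-fold changes.

Two printed rule variants exist and are both implemented; they are chosen
explicitly and never merged (`selection_rule("strictA")` /
`selection_rule("strictB")`):

* **strictA** — at least 40% regulation in one region and at least 30% in
  all others, adjusted p < 0.05. The sentence leaves it open whether the
  p-threshold binds one region or all; we apply it to **every** region.
  That reading makes rule A strictly stronger than rule B at a matched
  p-threshold — a containment the package asserts as a property test —
  whereas the one-region reading would not.
* **strictB** — at least 30% regulation with adjusted p < 0.10 in all, or
  in at least three, analysed regions.

Regulation must point the same way in every region where the probe is
measured; oppositely regulated probes are excluded from selection and
surfaced by `direction_report()`, which implements the separate
region-specific track (significant in two regions with opposite sign).
Probes missing from a region's table fail that region — the conservative
choice. Lowering any threshold can only grow the selected set.

## qPCR: 2^-ddCt relative quantification

`ddct_quantify()` averages technical duplicates on the Cp scale, subtracts
the housekeeping reference — one gene's Cp, or the arithmetic mean Cp of a
pair, which is the geometric mean on the expression scale — and converts
`rel = 2^-dCt`. Amplification efficiency is fixed at 2 per cycle, the
model's defining assumption. `fold_regulation()` calibrates to the group
with the smallest mean relative expression (reference fold exactly 1, all
folds >= 1 relative to it; the source states group-mean calibration rather
than a designated calibrator sample, and we follow that sentence). Group
dispersion is the SEM of per-sample folds, matching the mean+SEM figure
convention. Adding a constant to every Cp on a plate — a plate-wide
threshold shift — changes nothing, and the housekeeping pair is symmetric
in its two genes; both invariances are asserted exactly in the tests.

`ish_quantify()` implements the in-situ-hybridization arithmetic only:
per-section signal minus the background of a nearby non-expressing
structure, maximum over an individual's 3–6 sections; image densitometry
itself is out of scope.

## Variants: comparison, annotation, tallies, clusters

`diff_alleles()` globally aligns two allele sequences (Needleman–Wunsch,
affine gaps: match 1, mismatch −1, open 5, extend 1, via Biostrings) and
walks the alignment: mismatch columns are SNPs, each gap run is one
insertion or deletion **event** (events, not bases, are counted), typed
relative to the declared reference sequence, left-aligned, `N` columns
skipped. The alignment parameters are not results-critical: the function
is exercised on near-identical line alleles.

`gene_model()` describes one locus: ~2,500 bp promoter, exons with CDS
(hence UTR) boundaries, introns, and ~2,000 bp downstream enhancer region
(DER). Coordinates are 1-based inclusive; promoter offsets are negative
relative to the TSS. `annotate_variants()` assigns regions by interval
lookup and computes spliced-mRNA offsets by summing upstream exon lengths.
UTR status is carried in its own column while the region label stays
`exon-k`: the published accounting counts UTR-located exonic sites among
the exonic polymorphisms, so tallies by region label reproduce it while
the UTR information stays available.

`tally_variants()` produces the type-by-region contingency table with
margins; margins conserve the record count. `cluster_scan()` slides a
window of stated width anchored at variant positions (half-open) and
reports all maximal-count windows in position order; the maximum is
monotone in the window width. Because published cluster figures are
approximate ("about six variations … 230 bp") and their window anchoring
is undefined, comparisons against them are made at the documented widths
with the scan's own maxima.

`coding_consequence()` translates the affected codon under both alleles
(standard genetic code) and reports synonymous or missense; CDS indels are
flagged frame-affecting without an amino-acid call.

### The synthetic Ctsb reconstruction

The row-level variant table of the cathepsin B locus is not available in
machine-readable form, so the package ships a deterministic synthetic
reconstruction (`ctsb_variant_table()`,
`inst/extdata/ctsb_variants_synthetic.tsv`) that reproduces every
published marginal exactly — 76 SNPs / 8 insertions / 9 deletions; ten
SNPs and two insertions in the promoter; eight exonic sites, all SNPs, all
coding ones synonymous; ~6 variants in a 230 bp promoter window
(−2,269…−2,045), 18 in 550 bp of intron 3, 12 in 400 bp of intron 4, 12 in
350 bp of the DER; the bulk of sites in introns and DER — while individual
positions and alleles between those constraints are invented. The matching
gene model (`ctsb_gene_model()`) is likewise synthetic beyond its
published summary structure (ten exons, chromosome 14, Build-37-style
namespace, intron lengths under 2 kb, a 1,020 bp CDS). Neither object
should be used to interpret real coordinates.

## The synthetic-data module: what it emulates, and what it does not

All generators are deterministic functions of a `synth_config()`; the same
configuration gives bit-identical output. Defaults encode the emulated
study design: 24,192 probes per slide, ten replicate slides per region
(half dye-swapped), seven regions, 300 planted line-regulated probes with
fold ratios in [1.4, 3] (the selection rules' own threshold region and
above), at most six mice per line per single-channel batch, qPCR in
duplicate with eight samples per group and five housekeeping genes.

Choices the source does not state, fixed here once as calibration
decisions and exposed in the configuration:

* **Noise**: additive Gaussian on the log2 scale (multiplicative on the
  raw scale), spot SD 0.15 — a mid-range value for replicate spotted-array
  log-ratios that leaves a minimum-fold planted probe clearly but not
  trivially detectable with ten replicates; single-channel SD 0.2;
  qPCR well SD 0.1 cycles.
* **Dye-bias shape**: one full sine period scaled to the baseline A range,
  amplitude 0.3 log2 units — smooth, roughly mean-zero, and curved enough
  that only an intensity-dependent fit can remove it.
* **Sub-array offsets**: Gaussian, SD 0.1 log2 units across 48 blocks.
* **Baseline intensities**: log-uniform over A in [6, 14], populating all
  loess neighbourhoods.
* **Per-sample scale factors** (single-channel): Gaussian, SD 0.3 log2
  units, so between-array normalization is non-trivial.
* **qPCR loading offsets**: per-sample Gaussian, SD 0.5 cycles, shared
  between target and housekeeping wells so housekeeping normalization is
  doing real work.

Not simulated: scanner saturation, spot morphology, bead-level data, RNA
amplification artifacts, probe cross-hybridization, correlated
(spatially structured) noise, and biological replicate variance on the
two-colour path (slides are technical replicates, as in the emulated
design). Passing tests on this generator therefore demonstrate the
*statistical* correctness of the pipeline under its stated model — exact
family-wise control under exchangeability, unbiased fold recovery,
selection-rule behaviour — not robustness to every artifact of real
scanner data.

## Problem sizes and numerical choices in the checks

The test suite and `scripts/acceptance.R` run the pipeline at the study's
native scale where the property demands it (24,192 probes × 10 arrays per
run; seven regions for selection recall; complete 1,024-flip enumeration),
and at reduced scale elsewhere: the negative-control family-wise property
uses 100 seeded runs in the suite and 40 in the acceptance script; qPCR
calibration uses 200 seeded plates; the null calibration of the rank-test
chain uses 1,000 seeded tables. Seeds are derived arithmetically from a
single master seed so every run is reproducible.

Degenerate inputs are defined, not avoided: zero-variance probes rank
above all finite statistics; all-identical group values give H = 0 with a
warning; ties use mid-ranks with tie-corrected variances; ties in the
lowest-expressing qPCR group resolve by label order with a message; blocks
without usable spots pass through sub-array balancing unchanged with a
warning.

## Nonparametric group statistics

`kruskal_wallis()` wraps the tie-corrected H test (chi-square
approximation, df = k−1) with an optional exact permutation p-value by
complete enumeration for total n ≤ 10; `mann_whitney()` uses exact
enumeration for small tie-free samples and the tie-corrected normal
approximation otherwise; `sequential_bonferroni()` is Holm's step-down —
the standard referent of "sequential Bonferroni" — with monotone adjusted
p-values whose rejection set equals the step-down bounds.
`group_compare()` chains them in the reporting pattern of the emulated
study: pairwise tests run only when the omnibus p falls below a gate
(default 0.10), then Holm at α = 0.05. All tests are two-sided.

## Known limitations

* The permutation path needs at least two arrays, and its p-value
  granularity is `1/(1 + B)`; with few arrays the smallest achievable
  adjusted p may exceed conventional thresholds.
* The moderated-t path assumes two groups with n ≥ 2 each and a common
  variance model per probe; no array weights or batch covariates.
* `diff_alleles()` reports gap positions up to the left-shift ambiguity
  inherent in aligning repeats; round-trip tests acknowledge this.
* The headline expression findings of the emulated study depend on its
  deposited array data and are not recomputable here; the package's claims
  about them are limited to what the synthetic-truth properties establish.
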