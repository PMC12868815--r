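---
title: "Methods: spot QC, tissue geometry and spatial organization statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spot QC, tissue geometry and spatial organization statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungspatial)
```

## Scope

`lungspatial` analyses 10x Visium sections of developing tissue — the
motivating system is the human prenatal lung across the pseudoglandular
(6–16 weeks) to canalicular (17–26 weeks) transition — through four
connected stages:

1. **image-based spot QC**: eosin optical-density conversion, stain-vector
   estimation, per-spot quantile filtering of tissue-sparse spots, and a
   minimum RNA-count filter;
2. **tissue geometry**: hex-lattice edge labelling, tissue-border
   selection, radial border distances and the peripheral region;
3. **spatial organization**: per-spot-type Ripley's K/L with
   random-labelling envelopes, aggregated across samples into stage-level
   curves by local polynomial regression;
4. **composition statistics**: per-sample spot-type frequencies with
   rank, t and permutation tests, pseudobulk aggregation and rank-based
   sex-signature scoring.

A synthetic study generator produces complete Space Ranger-style bundles
with known ground truth, so every stage is testable end to end without
access to real sections.

## The capture lattice

Visium spots are 55 µm discs at 100 µm center-to-center spacing on a
hexagonal array, leaving a 45 µm interstitial gap. The package uses the
standard parity indexing: a spot exists at `(row, col)` iff `row + col`
is even, with the six neighbours at `(row, col ± 2)` and
`(row ± 1, col ± 1)`. This matches the dialect of
`tissue_positions_list.csv`, so real position tables round-trip through
the same code paths as synthetic ones. Micron coordinates place columns
at half the spacing and rows at `sqrt(3)/2` of it; pixel centers are the
micron centers divided by the image scale and rounded, which keeps
nearest-neighbour pixel distances within half a pixel of the nominal
spacing.

The per-sample image scale (µm/px) is the mean of two ratios — physical
over pixel diameter for the spot (55 µm) and the fiducial (85 µm, a
vendor constant not printed in sample metadata and therefore
configurable). Discordance above 1 % between the two channels is
reported as a warning rather than an error, since either channel alone
is a usable scale.

## Image-based spot QC

**Optical density.** Channel intensities are converted by Beer–Lambert:
`OD_c = -log10((I_c + 1)/I0)`, clipped at zero. The one-unit guard
avoids `log(0)` and sits below 8-bit quantization noise; it also makes
OD exactly zero at background intensity. The synthetic renderer uses the
inverse model with floor quantization to 8 bits; together the two bound
the round-trip OD error by `log10((I+1)/I) ≤ 0.017` for OD ≤ 1.

**Stain estimation.** Transparent pixels are removed and the unit
eigenvector of the covariance of the remaining OD triplets, sign-fixed to
positive mean projection, is taken as the eosin direction. Transparency
is defined on the *mean*-channel OD (default β = 0.15): eosin's red
component is ≈ 0.09, so a per-channel threshold at the conventional 0.15
would discard every tissue pixel, while the mean-OD criterion removes
background only. On sections where eosin explains ≥ 90 % of OD variance
the estimate is within a few degrees of truth (the acceptance suite
measures ≈ 1°).

**Normalization.** OD is projected on the eosin vector and rescaled so
the 0.99 quantile of non-transparent projections equals 1.0. Workflows
of this kind anchor staining intensity to a "reference pixel value"
without standardizing which one; a high quantile of the projection
distribution is the conventional scale anchor and makes the output
exactly invariant to global staining intensity and exposure.

**Tissue-sparse filter.** Per spot, the 0.90 quantile (linear
interpolation between order statistics — R type 7, pinned so tests are
bit-stable) of normalized eosin OD within the 27.5 µm capture disc is
compared against a threshold; below it the spot is reclassified as
background for all downstream geometry. No numeric threshold is
published, so the default is the Otsu split of the per-sample quantile
distribution (overridable). The Otsu implementation splits plateaus of
maximal between-class variance at their midpoint, so a clean bimodal
separation thresholds in the middle of the gap rather than at its edge.

**Count filter and edge labelling.** Spots with fewer than 200 RNA
molecules are removed. Filter order is: vendor in-tissue flag → sparse
filter → count filter; a retained spot is an *edge* spot iff any of its
six lattice neighbours is background or off-array, computed on the final
retained set. The pipeline logs spot counts before and after each
filter.

## Border and peripheral region

Tissue-border spots are the subset of edge spots representing the organ
surface (the pleura, in lung sections). The faithful mode reads a manual
selection file, validating every id against the edge set. Because manual
selection is irreproducible, an automated fallback returns the outer
boundary of the largest connected tissue component — edge spots adjacent
to background connected to the off-array exterior — which on a solid
section equals the manual "whole outline" choice and deliberately
excludes interior holes (vessels, airways).

Radial distance is the Euclidean center-to-center distance in
full-resolution pixels from each retained spot to its nearest border
spot. The peripheral region is the spots within 500 µm (inclusive —
"not greater than"); a fixed 150 px mode is also provided since at the
nominal 10/3 µm/px the two are the same cutoff. The comparison carries a
relative epsilon so that 150 px × 10/3 µm/px counts as exactly 500 µm
under floating point. At 100 µm spacing the peripheral band is five
lattice rings.

## Ripley's L per spot type

For the spots of one type, with `n ≥ 2` points in a window of area
`|A|`:

    K(r) = |A| / (n (n-1)) * sum_{i != j} 1(d_ij <= r),
    L(r) = sqrt(K(r) / pi)

evaluated on 50 equally spaced radii from 0 to half the window's shorter
side (local through whole-sample scales). The default estimator applies
**no edge correction**: the null model conditions on the same retained
lattice (labels permuted over fixed positions), so the edge deficit is
identical in observed and null curves and cancels in the comparison —
and since spot types are categorical labels on a fixed 55/100 µm
lattice, cell-density confounding is absent by construction. A
translation correction is available; it is the right choice when L is
read against the CSR reference `L(r) = r` directly. In that absolute
reading the lattice's ring structure dominates below roughly five
spacings, so CSR recovery within 5 % holds for
`5 * spacing ≲ r ≤ window/2` — the regime the property tests pin.

Raw `L` is reported (with `L - r` trivially available); the envelope is
the pointwise 2.5/97.5 percentile band over label permutations (default
99), deterministic given a seed. Types with fewer than two spots are
skipped with a message.

**Stage aggregation.** Per-sample curves, expressed in microns so
windows are comparable, are pooled per (stage, type) and smoothed onto a
common 50-point grid with a hand-written loess-type smoother: tricube
weights over the `ceiling(span * n)` nearest observations, local linear
fit, span 0.75. The smoother is pinned by a weighted-least-squares
oracle in the tests; query points whose window holds fewer than two
usable observations yield `NA`, and exact duplicate-x windows fall back
to the local mean.

## Composition statistics

Frequencies are per-sample spot-type proportions over the retained,
annotated spots, zero-completed to the full type vocabulary.

- **Stage comparison** (per type): Wilcoxon rank-sum. For combined
  n ≤ 12 — the scale of a 6 + 6 study — the two-sided p is computed by
  full enumeration of all `choose(n, nx)` assignments of the observed
  mid-ranks, so ties are exact; larger samples use the tie-corrected
  normal approximation. Benjamini–Hochberg adjustment is applied across
  the 10 types (raw p retained), since testing each type separately is a
  multiplicity the source procedure leaves unaddressed.
- **Condition comparison**: permutation test with the omnibus statistic
  `T = sum_types (mean freq_1 - mean freq_2)^2` — a standard
  exchangeable choice; the reference procedure names no statistic. All
  distinct label splits are enumerated when they number at most
  `n_perm` (a 6 + 6 design has 924, so the default 999 makes the test
  exact and seed-free); otherwise `n_perm` random permutations with the
  `(1 + k)/(n_perm + 1)` estimate.
- **Peripheral contrast**: Student's t on per-sample frequencies of a
  target type in peripheral vs non-peripheral spots, paired by default
  (each sample contributes both regions); the unpaired pooled-variance
  form is available. Zero variance of differences is an explicit error.
- **Pseudobulk**: integer count sums per (sample, cluster), conserving
  the grand total exactly — the input expected by sample-level
  differential expression tools, whose model fitting is out of scope
  here.
- **Sex calling**: the male signature (RPS4Y1, UTY, KDM5D, DDX3Y, USP9Y,
  VCX, VCY) is scored per sample with a rank-based (UCell-style)
  statistic: genes ranked by decreasing expression, mid-rank ties, ranks
  beyond `r_max` (default 1500) clamped to `r_max + 1`, and
  `score = 1 - U'/(n_sig * r_max)` clipped to [0, 1]. The score depends
  only on ranks, hence is invariant to any monotone transform of
  expression. Samples score male above 0.2 (configurable); a female
  sample's silent Y genes sit at the clamped bottom ranks and score
  ≈ 0.002.

## The synthetic study generator

Defaults emulate a 12-sample, two-stage design (six pseudoglandular,
six canalicular; 5 male / 7 female; two trisomy-21 samples per stage)
over ten niche types named for mid-gestation lung compartments. Per
sample it emits the full bundle: positions table, scale factors, a
rendered two-stain PNG, MatrixMarket counts with sidecars, ground-truth
spot annotations, and a study-level sample sheet. One study seed expands
to per-sample sub-seeds by fixed arithmetic, so studies are
byte-identical across runs and samples are mutually independent.

**Type fields.** Type centers are drawn uniformly over the lattice box,
in numbers proportional to the target proportions, and each spot samples
its label from Gaussian-kernel mixture weights
`P(k|s) ∝ (p_k/m_k) Σ_j exp(-d(s, c_jk)^2 / (2σ^2))`. As σ → 0 this is
exactly "label by nearest center"; as σ → ∞ the label distribution
converges to the configured proportions. The naive
jitter-then-nearest-center construction lacks the second property (a far
point only ever resolves to convex-hull centers), which is why the
mixture form is used: the generator must deliver both tight clustered
domains *and* exact composition control.

**Stage contrast.** The canalicular stage carries a +0.15 shift in
`distal_parenchyma` (with compensating mesenchymal decrease) and tighter
clustering. Dispersions are σ = 600 µm (pseudoglandular: diffuse,
poorly separated domains) vs 150 µm (canalicular: discrete compartments
about 1.5 spot-spacings wide). The pair is deliberately wide: domain
prevalence itself modulates apparent clustering — a type at 45 %
prevalence tiles half the window and its pattern moves toward the full
lattice, i.e. toward CSR — so a narrow dispersion contrast would be
partially cancelled by the composition shift. The chosen pair expresses
the developmental regime the analysis is meant to detect (higher
canalicular L at local and whole-sample scales) over and above that
prevalence effect.

**Counts.** Negative-binomial (baseline mean 4 per gene, dispersion
θ = 2) over 10 markers per type (5-fold elevated in their own type),
the seven Y-signature genes (3-fold baseline in males, structurally zero
in females), and 400 background genes. Tissue-sparse spots (5 % of
in-tissue spots) have all means scaled by 0.02, placing their totals two
orders below the 200-count threshold, while non-sparse totals
(≈ 2000) clear it with probability ≈ 1.

**Images.** Per-spot eosin levels 0.9 ± 0.08 (uneven staining) with
within-spot texture, a faint hematoxylin component (U(0, 0.08)), and
sparse spots at eosin 0.02 are painted as capture-disc disks and
rendered by the Beer–Lambert forward model on a transparent background
at I0 = 255. Eosin thus explains ≳ 90 % of OD variance, the regime the
stain estimator is specified for.

**What the generator does not emulate** — and hence what passing tests
do not certify about real sections: histological morphology (domains
are kernel blobs, not branching airways), chromatic aberration, uneven
illumination and scanner noise, segmentation artefacts at the tissue
boundary, empty-droplet/ambient contamination in counts, and any
trisomy-21 expression signal (the condition axis is a pure null, which
is also what makes it usable for calibration).

## Numerical choices

- Quantiles: linear interpolation (R type 7) everywhere.
- Image quantization: floor to 8 bits; OD guard ε = 1 intensity unit.
- Otsu: 256 bins; plateau of maximal between-class variance split at its
  midpoint.
- Peripheral boundary: inclusive, with a 1e-9 relative epsilon.
- Wilcoxon exact limit: combined n ≤ 12; two-sided p by tail doubling,
  capped at 1.
- Permutation test: exhaustive when `choose(n, n1) ≤ n_perm` (p is then
  `#{T ≥ T_obs}/n_splits` with the observed split included), otherwise
  Monte Carlo with the +1/+1 correction.
- Degenerate inputs fail loudly: constant OD covariance, empty border
  sets, zero-variance paired differences, single-condition permutation
  designs, types with fewer than two spots (skipped with a message).

## Problem sizes

The test and acceptance suites run at desk scale, chosen so the whole
suite completes in a few minutes on one core: 44 × 44 lattices
(≈ 970 spots) for stage-curve recovery over 20 replicates, 63 × 63
(≈ 2000 spots per sample, 12 samples) for composition-shift recovery
over 50 replicates, 99-permutation envelopes over 50 calibration
trials, 1000 null trials for permutation-test calibration, and full
generated studies on 16–20 row lattices for end-to-end checks.
Dataset-scale quantities from real studies (tens of thousands of spots,
genome-wide genes) are inputs the same code paths accept but are not
reproduced at this scale.

## Limitations

Ripley curves use a rectangular (or convex-hull) window around retained
spots; strongly non-convex sections inflate `|A|` and depress K
uniformly — harmless against the conditioned null, but visible in
absolute readings. Distances to the border are straight-line, not
within-tissue geodesics. The automated border is a topological
surrogate for an anatomical (pleural) judgement: on sections where the
pleura is only part of the outer boundary, the manual file remains the
faithful mode. Bivariate (cross-type) K, inhomogeneous K and formal
functional testing between stage curves are out of scope.
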