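---
title: "Brain dynamics at event boundaries: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain dynamics at event boundaries: models, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventseg)
```

`eventseg` analyses BOLD responses around perceived event boundaries in
continuous auditory stimulation — the setting where listeners mark segment
boundaries in real time while independent subjects are scanned listening to
the same stimulus. This vignette is the package's account of the underlying
models, why the defaults are what they are, and what the validation results
do and do not show.

## The boundary-salience regressor

Boundary perception is graded: some transitions are marked by nearly every
listener, others by a few. Pooling all marker times across participants and
smoothing them with a Gaussian kernel produces a continuous salience series

$$d(t) = \sum_{m} \frac{1}{h}\,\varphi\!\left(\frac{t - t_m}{h}\right),$$

whose height measures cross-listener consensus. We keep the density
*unnormalized* (it integrates to the total marker count) so salience is
comparable across stimuli with different marker counts; `normalize = TRUE`
is available. The default bandwidth is `h = 2` s — one repetition time, the
temporal resolution at which lagged effects are probed — and it is an exposed
argument, never a constant buried in code. The density is evaluated on a
fine grid (default 0.1 s), then linearly interpolated at scan frame onsets
(0-based scan index, time `i * TR`).

Markers can also be pooled per listener group (`groups =` argument of
`estimate_salience()`); the default pools across groups, which is the
convention the rest of the pipeline assumes.

## Lagged GLM and pooling

The design matrix holds HRF-convolved copies of the scan-grid regressor
shifted by −1, 0 and +1 scans. With TR = 2 s these probe responses up to 2 s
before and after the boundary. Two decisions matter here:

* **Joint fit.** All three lag columns enter one model. Lagged copies of a
  smooth regressor are nearly collinear (pairwise correlations ~0.95 after
  HRF convolution); fitting them separately would count the shared variance
  three times. A per-lag mode (`joint = FALSE`) exists for comparison.
* **One-sided p pairs.** Each voxel/lag yields `p_pos` and `p_neg`
  (summing to 1), and Fisher's combined test −2 Σ ln p ~ χ²(2k) pools
  activations and deactivations across the k subjects separately, which is
  what red/blue activation–deactivation group maps require.

The HRF is the canonical double-gamma (gamma shapes 6 and 16, undershoot
ratio 1/6, 32 s support, unit sum), sampled at TR. An identity option exists
so exactness tests can bypass hemodynamics. Whether the boundary regressor
should be convolved at all is a genuinely open choice in this design; the
default is convolved, with `convolve = FALSE` available.

The RMS amplitude envelope is removed from every voxel by OLS projection
before any analysis, and `check_confound()` reports the regressor–RMS
Pearson and Spearman association so loudness explanations can be ruled out.

## Nonparametric inference

Lag and group contrasts use Wilcoxon tests. The within-subject lag contrast
is implemented as the two-sample rank-sum test (the convention of the
analyses this package operationalizes) with a paired signed-rank variant
behind `method = "signed_rank"`, since lags are in fact paired within
subject. Exact null distributions are used for n ≤ 25 without ties
(`psignrank`/`pwilcox`); ties fall back to mid-ranks with a tie-corrected
normal approximation. Exactness against full enumeration is part of the test
suite for all n ≤ 8.

Cluster-extent FWE correction uses the max-statistic permutation method:
voxelwise statistics (one-sample t for sign-flip, rank-sum z for
label-shuffle) are thresholded at an uncorrected forming p (default 0.001
for GLM maps; 0.05 for component group maps, following the looser convention
used for ICA group differences), suprathreshold voxels are labelled into
26-connected components (6-connectivity available), and each observed
cluster's extent is referred to the permutation distribution of the maximum
extent with the add-one estimator, so corrected p-values are never zero.
Under the null the method controls FWE strongly; the validation suite checks
the realized FWE over 100 null datasets.

FDR adjustment is Benjamini–Hochberg throughout (`stats::p.adjust`).

## Group spatial ICA and GICA3

Subject data (scans × voxels, voxels centred over time) are reduced to
`subject_dim` temporal principal components per subject, concatenated, and
reduced again to `group_dim` group components. Spatial ICA maximizes
non-Gaussianity of the maps over voxels by a symmetric FastICA fixed point
with the log-cosh contrast (α = 1, exposed). Numerical choices:

* convergence tolerance 1e−7 on the rotation criterion, 500 iterations,
  5 random orthonormal restarts per fit, all seeded — decompositions are
  bit-for-bit reproducible from (data, order, seed);
* near-Gaussian (noise) components can trap the plain symmetric iteration in
  a period-2 limit cycle; the engine detects this (or a stall beyond a third
  of the budget) and switches to a damped, sign-aligned update, which
  restores convergence without moving the fixed points;
* components are sign-fixed (peak-magnitude voxel positive), ordered by
  explained variance, and z-scaled over voxels.

GICA3 back-reconstruction projects each subject's reduced data through the
group unmixing matrix, scaled so the mean of the subject maps equals the
group map *exactly* — an algebraic identity here, asserted at 1e−6 in the
tests. Subject time courses are the back-projection of the mixing matrix
through the subject and group PCA bases.

Model order is not assumed: `scan_model_orders()` fits a range (default
5/10/15/20 at desk scale; the range is a user choice) and matches components
across orders by greedy absolute spatial correlation (threshold 0.7),
yielding a stability score per component. Stimulus-locked networks recur
across orders; noise components do not.

**Lag profiling.** Each subject's component time course is regressed
*jointly* on all lagged regressors and the per-lag partial betas are tested
across subjects with one-sample signed-rank tests. The joint fit is
essential: with near-collinear lagged regressors, marginal per-lag betas are
all strongly positive for any stimulus-locked component, every lag saturates
the signed-rank p at its minimum attainable value, and the classification
rule loses all discrimination. Partial betas isolate each lag's unique
contribution. A component is classified *early* if its minimum-p lag is −1,
*transition* if 0 or +1 (ties toward 0), *unrelated* if nothing clears
`alpha` (default 0.05).

## Difference-of-influence Granger causality

For component time courses x (early) and y (transition), bivariate VAR
models are fitted by OLS for orders 1..`max_order` (default 10) on the
common sample; AIC selects the working order (BIC is recorded alongside).
The influence of x on y is the Geweke-style log variance ratio
`F_{x→y} = ln(RSS_restricted / RSS_full)` comparing y's autoregression with
and without x's lags; it is invariant to rescaling either series, and series
are variance-normalized before fitting purely for numerical stability.

Hemodynamic blurring and slow sampling make raw Granger measures spuriously
bidirectional; the difference of influence `DOI = F_{x→y} − F_{y→x}`
cancels the shared component. Group inference is a one-sample signed-rank
test of subject DOIs against zero (the per-participant DOI estimates form
one sample), FDR-adjusted when several network pairs are tested; direction
is assigned by the median DOI sign only when the adjusted p clears `alpha`
(default 1e−4).

A limitation worth stating: DOI cancels symmetric spurious influence, not
*lead–lag structure shared through the stimulus*. If two networks are driven
by the same regressor at staggered lags, the earlier network "Granger-causes"
the later one even with no neuronal coupling. For this reason the package's
causal-calibration experiments simulate the VAR mechanism in isolation
(`simulate_var_pair()`), where the null arm (zero coupling) is exact; on
full volume simulations the planted coupling and the staggered drive push
the DOI in the same (planted) direction. No hemodynamic deconvolution is
applied before the VAR, matching the analysis this package operationalizes.

## The synthetic-data generator

The generator is the package's ground-truth instrument, not a fixture. It
emulates: ~36 behavioural participants (desk default 24) marking boundaries
with probability equal to each boundary's salience, Gaussian timing jitter
(SD 0.5 s) and uniform false alarms (0.5/min); an RMS-like smooth positive
confound with an exactly controlled correlation to the true salience series
(default 0.05, the weak association regime this design targets); two
disjoint Gaussian-blob networks (thresholded at 1% of peak) whose time
courses load on the HRF-convolved lagged regressor with weights
early = (1, 0, 0) and transition = (0, 1, 0.8) across lags (−1, 0, +1); a
scalar group gain (musicians 1.5 vs nonmusicians 1.0) on those weights;
unidirectional VAR coupling 0.4 from the early to the transition time
course; and AR(1) (φ = 0.3) Gaussian voxel noise scaled so the strongest
in-network voxel has signal SD / noise SD = `snr` (default 1). Desk scale is
a 20×20×10 grid, 150 scans at TR 2 s, 12+12 subjects; boundaries are placed
every 28 s with cycling saliences 1/0.55/0.85/0.4/0.7, a plausible phrase
rate for multi-genre naturalistic music. Everything is reproducible
bit-for-bit from the config seed through named substreams.

What the generator does *not* emulate — anatomy, spatial noise correlation,
motion, physiological noise, genre structure, hemodynamic variability across
regions — bounds what passing tests show: they validate the estimators and
their calibration under the stated generative model, not performance on real
tissue.

## Small-sample caveats

Two desk-scale phenomena are documented rather than hidden:

* **Lag-map clustering.** Group-mean per-lag maps from the joint GLM inherit
  the negative off-diagonal estimation covariance of the collinear design
  columns. With few subjects this noise covariance, not the planted map
  similarity, determines the dendrogram. The clustering operation itself is
  validated on maps with a planted correlation structure (first merge joins
  the 0.8-correlated pair in 100/100 seeds); the pipeline reports the
  dendrogram but end-to-end assertions at 8+8 subjects do not fix its shape.
* **Saturated signed-rank p-values.** With n subjects the smallest two-sided
  signed-rank p is 2/2^n; at n = 24 the lag-profile p-values of strong
  components sit at this floor, which is why classification uses partial
  betas (see above) and why reported p-values at desk scale should be read
  as "at floor", not as continuous evidence measures.

## Problem sizes used in validation

The validation suite runs at the desk scale above: the planted-recovery
checks use one 24-subject dataset each; classification rates use 50
generator seeds; DOI power and null calibration use 200 replicates of 36
subjects × 200 scans each (100 in the acceptance script); FWE control uses
100 null datasets × 500 permutations (50 in the script); exactness checks
enumerate all sign patterns / group assignments at n ≤ 8 and compare the KDE
against brute-force kernel sums on 100 random marker sets.
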