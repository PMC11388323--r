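# eventseg

Analysis pipeline for brain dynamics at perceived event boundaries in
naturalistic listening fMRI.

When listeners hear continuous music they parse it into segments, and groups
of listeners agree remarkably well on where the boundaries fall. `eventseg`
implements the full analysis chain for studying what the brain does around
those moments, for researchers working with real-time segmentation tasks and
BOLD time series:

1. **Boundary-salience regressor.** Listeners' real-time boundary markers are
   pooled across participants by Gaussian kernel density estimation. The
   unnormalized density `d(t) = Σ_m φ((t − t_m)/h)/h` (one term per marker,
   bandwidth `h` in seconds) is a continuous measure of cross-listener
   consensus: high where many listeners marked a boundary, low elsewhere.
2. **Confound control.** The per-scan RMS amplitude envelope of the stimulus
   is regressed out of every voxel time series, and the regressor-vs-RMS
   association is reported (Pearson and Spearman), so salience effects are
   not loudness effects.
3. **Lagged GLM.** Each voxel is regressed jointly on HRF-convolved copies of
   the boundary regressor shifted by −1, 0 and +1 scans (TR = 2 s), probing
   pre-boundary, at-boundary, and post-boundary responses. Per-subject
   one-sided p-values are pooled with Fisher's combined-probability test
   (−2 Σ ln p ~ χ²(2k)); lag and group contrasts use Wilcoxon rank tests with
   permutation cluster-extent FWE correction.
4. **Group spatial ICA with GICA3.** Two-step PCA reduction (subject, then
   group) followed by symmetric FastICA over voxels across a range of model
   orders, with GICA3 back-reconstruction of subject-specific component maps
   and time courses (the mean of the subject maps reproduces the group map
   exactly). Components are profiled across lags and classified as *early*
   (pre-boundary), *transition* (at/post boundary) or unrelated.
5. **Difference-of-influence Granger causality.** For the early/transition
   component pair, per-subject bivariate VAR models (order chosen by AIC,
   BIC recorded) yield Geweke-style influence terms
   `F_{x→y} = ln(σ²_restricted/σ²_full)`, and the difference of influence
   `DOI = F_{x→y} − F_{y→x}` — robust to the spurious bidirectionality that
   hemodynamic blurring induces — is tested across subjects with a
   signed-rank test, FDR-adjusted over network pairs.

Because real task fMRI data of this kind are access-restricted, the package
ships a first-class synthetic-data module that plants known ground truth —
marker point processes with salience-dependent participation, an RMS-like
confound with controlled correlation, two spatial networks with lag-specific
loadings and unidirectional causal coupling, AR(1) voxel noise — so every
stage can be validated against what was planted.

## Worked example

```r
library(eventseg)

cfg   <- sim_config(n_subjects = 8L, n_scans = 150L,
                    grid_shape = c(14L, 14L, 7L), seed = 42L)
truth <- default_ground_truth(cfg)

report <- run_pipeline(pipeline_config(
  simulate = TRUE, n_scans = 150L, seed = 42L,
  n_permutations = 120L, ica_orders = c(4L, 6L),
  subject_dim = 20L, group_dim = 12L,
  sim = list(n_subjects = 8L, grid_shape = c(14L, 14L, 7L))))
print(report)
```

```
Boundary-analysis pipeline summary
==================================
Confound check: Pearson r = 0.008 (p = 0.921), Spearman rho = 0.049 (p = 0.552)
GLM clusters per lag: lag_-1: 2, lag_0: 1, lag_1: 2
ICA classification: IC1=transition, IC2=early, IC3=unrelated, IC4=unrelated, IC5=early, IC6=unrelated
GCA: early_causes_transition (median DOI +0.3153, p_fdr = 3.05e-05)
Lag-map clustering first merge: lag_-1 + lag_1
```

Reading the output: the boundary regressor is essentially uncorrelated with
stimulus loudness (r ≈ 0.01, n.s.), so boundary effects are not amplitude
effects. The GLM finds significant clusters at every lag (the two planted
networks). ICA recovers one component engaged *before* boundaries (early) and
one engaged *at/after* them (transition), and the Granger analysis recovers
the planted direction of influence: the early network drives the transition
network (positive median DOI, FDR-adjusted p ≪ 0.05). The lag-map dendrogram
is also reported; at this small sample size its structure reflects the
estimation covariance of the collinear lag columns (see the methods
vignette).

## Layout

- `R/` — synthetic data (`simulate_*`), regressor (`estimate_salience`,
  `build_lag_design`), GLM (`fit_subject_glm`, `fisher_combine`), inference
  (`cluster_correct`, `wilcoxon_*`, `fdr_adjust`, `cluster_lag_maps`), ICA
  (`reduce_two_step`, `fit_spatial_ica`, `back_reconstruct_gica3`,
  `profile_lag_significance`), Granger (`select_var_order`,
  `granger_influence`, `doi`, `group_doi_test`), I/O and pipeline
  (`read_volumes`, `run_pipeline`).
- `vignettes/boundary-pipeline.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical decisions, limitations.
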