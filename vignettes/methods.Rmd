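---
title: "Methods: voxelwise resting-state metrics, GRF inference and SVM classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxelwise resting-state metrics, GRF inference and SVM classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`boldmetrics` implements a multilevel resting-state fMRI discrimination
pipeline for two-group (patient vs. control) BOLD cohorts: five voxelwise
local metrics and seed-based network connectivity maps are computed per
subject, compared between groups with a covariate-adjusted voxelwise GLM
under Gaussian-random-field (GRF) cluster-extent correction, reduced to
ROI-mean features over the surviving clusters, fed to an RBF-kernel SVM with
nested cross-validated hyperparameter search, and interpreted with
Shapley-value feature attributions. Because clinical scans are rarely
shareable, the package ships a synthetic 4D BOLD cohort generator with
injectable, per-metric group effects, so every stage of the pipeline is
testable against a known ground truth.

# The synthetic cohort generator

Each subject's BOLD matrix (time x voxels) is the sum of

* independent per-voxel band-limited (0.01-0.08 Hz) Gaussian oscillations
  (`background_amp`, default 0.6 in white-noise SD units) -- the
  "resting-state signal" the metrics interrogate;
* two global nuisance time courses with smooth random spatial weights
  (`nuisance_amp`, default 0.5), standing in for white-matter/CSF signal;
* a motion-coupled drift built from the subject's simulated 6-parameter
  random-walk motion trace (`drift_coupling`, default 0.4);
* white Gaussian noise (`sigma_white` = 1, the unit of everything else).

Defaults follow the acquisition regime the pipeline targets: TR = 2 s,
180 volumes of which the first 10 are discarded, and a desk-scale
24 x 24 x 16 grid of 3 mm voxels that keeps the temporal regime of a real
acquisition at a spatial size where whole-pipeline tests run in seconds.
Ages are drawn Normal(43, 12) truncated to [18, 80] and sex is a fair coin:
enough covariate variation to exercise the GLM without imitating any real
cohort. Motion steps default to 0.02 mm / 0.02 degrees per volume so that no
subject trips the 2 mm / 2 degree exclusion rule; `force_motion_violator`
inflates the steps to test the exclusion path.

Injectable effects (`effect_spec`) raise, inside a spherical region and for
the patient group only (or the control group, for `patient_down`), the
generative parameter the corresponding metric family measures: extra
low-frequency amplitude (fALFF), a shared in-region low-frequency source
(ReHo), the same source additionally coupled at 0.3 x magnitude to all gray
matter (degree centrality), shared with the mirrored region (VMHC), or
shared with a partner sphere (seed FC). Magnitudes are tool parameters --
the source publication gives no generative account of patient physiology,
so no magnitude claims to estimate a clinical effect size.

What a green test on synthetic data establishes is computational
correctness and statistical calibration of the pipeline, not clinical
validity: the generator has no hemodynamic response model, no anatomy, no
scanner artefacts, and its "gray matter" is a smooth ellipsoidal blob
calibrated so 60% of the grid exceeds the 0.2 probability cutoff.

# Preprocessing

The published post-realignment order is fixed in `preprocess_subject`:
discard 10 volumes, regress the Friston-24 motion expansion (6 parameters,
their one-volume lags, both sets squared; first lag row zero-filled) plus
optional tissue nuisance courses, then band-pass 0.01-0.08 Hz. Band-passing
is implemented as linear detrend followed by rectangular frequency-domain
masking, which makes the passband contract exact at Fourier bin frequencies.
Framewise displacement uses the Power convention: summed absolute backward
differences with rotations converted to arc length on a 50 mm sphere. The
motion exclusion rule reads "exceeds 2.0 mm translation or 2.0 degrees
rotation" as per-axis absolute maxima of the realignment parameters.

# Local metrics: conventions and contested choices

**fALFF** is the ratio of summed square-root power over 0.01-0.08 Hz to the
summed square-root power over the full positive-frequency range, DC bin
excluded. It is computed from the nuisance-regressed but *not* band-passed
series: band-passing first would make the ratio degenerate (the denominator
would hold no out-of-band energy). Spatial smoothing (6 mm FWHM) is applied
*before* fALFF and *after* ReHo/DC/VMHC/FCS, matching the toolbox convention
the published pipeline used; `compute_local_metrics` records the order per
metric so tests can assert it.

**ReHo** is Kendall's coefficient of concordance of a voxel's time series
with its 26 neighbors. The source text states K = 26 "neighboring voxels",
but with rank sums taken over all 27 series the KCC normalization must use
the number of concordant series (27 for interior voxels), otherwise w = 1 is
unattainable and w can exceed 1; the implementation therefore uses the
number of in-mask series in the neighborhood (center included), which also
gives boundary voxels a well-defined value. Ties take average ranks;
constant series give w = 0 with a warning.

**Degree centrality** sums positive correlations above r = 0.25 ("weighted"
degree; a binary edge-count variant is available by flag, since the source
text is internally inconsistent between "sum the connections" and "weighted
DC"). **FCS** divides the sum of suprathreshold (r > 0.2) Fisher-z values by
the full N - 1 as printed -- flagged, because part of the literature divides
by the suprathreshold count instead. **VMHC** correlates each voxel with its
mirror across the mid-sagittal plane after symmetrizing the mask by
intersection with its own mirror; the raw map is mirror-symmetric by
construction (a property the tests assert exactly).

**Standardization.** The source text says all maps were "transformed to
z-scores using Fisher's z-transform", but fALFF, ReHo and DC are not
correlations and atanh of, say, a ReHo of 1 is infinite. The package
standardizes correlation-valued maps (VMHC, seed FC) with atanh (clipped at
|r| = 1 - 1e-7) and the others by within-mask z-scoring; both routes are
exposed through `standardize_map(method=)` so the literal reading remains
runnable.

# Seed-based network maps

Twelve networks with published seed coordinates (6 mm radius spheres, world
mm through the grid affine) are built in; the seed mean is taken over
seed-and-gray-matter voxels and correlated with every gray-matter voxel,
then Fisher z-transformed. On desk-scale grids the full-FOV coordinates fall
outside the volume; `remap_seeds` rescales them linearly into the grid's
bounding box, preserving the left/right and anterior/posterior layout.
Whether the published pipeline used smoothed or unsmoothed data for seed FC
is unstated; the package computes it on the preprocessed series and smooths
the resulting map alongside the other metrics.

# Group statistics and GRF cluster correction

Per voxel, ordinary least squares on [intercept, group, age, sex, mean FD]
gives the group-coefficient t-statistic with df = n - 5 (equal to the pooled
two-sample t when covariates are absent, asserted to 1e-10). Sex enters as
0/1; the voxel test is two-sided (the published cluster tables contain both
signs) and clusters are labelled separately per sign under 26-connectivity
(6/18 selectable).

Residual smoothness is estimated from the lag-1 spatial autocorrelation of
standardized residuals: under a Gaussian autocorrelation model
`FWHM_vox = sqrt(-2 ln 2 / ln rho1)`, floored at one voxel. The floor is a
deliberate choice: a lattice cannot express sub-voxel smoothness, the
Gaussian-ACF estimator is exact in expectation for smoothed noise, and the
floor makes unsmoothed white noise report the voxel size rather than zero.
The common gradient-variance estimator overestimates white-noise smoothness
by ~18% and was rejected for that reason. RESELs are mask volume divided by
the product of per-axis FWHMs.

Cluster-level inference Gaussianizes the t-field and uses the expected-
Euler-characteristic cluster count together with the exponential
cluster-size tail: `E[m] = R (4 ln 2)^{3/2} (2 pi)^{-2} (u^2 - 1)
exp(-u^2/2)`, `P(n >= k) = exp(-beta k^{2/3})` with
`beta = (Gamma(5/2) E[m] / E[N])^{2/3}`, cluster p
`= 1 - exp(-E[m] P(n >= k))`. At voxel p < 0.001 / cluster p < 0.01 the
family-wise false-positive rate measured over 200 null desk-scale cohorts
stays below 0.05 (an acceptance test).

**Circularity.** The published pipeline derives ROIs from *all* subjects
before the train/test split, which leaks group information into the feature
definition. `group_analysis` reproduces that behavior by default and offers
`split_aware =` training-row indices to derive clusters from training
subjects only; the difference matters on null data, where the default mode
inflates apparent classification performance.

# Classification

Features are min-max rescaled to [0, 1] with ranges fitted on training rows
only (the source text calls the scaler min-max yet describes zero mean and
unit variance; min-max is implemented as named). Hyperparameters come from
the printed 9 x 5 grid (C in decades 1e-4..1e4, gamma 1..1e-4), selected by
stratified 5-fold cross-validation on the training split using mean
validation AUC, ties broken toward smaller C then smaller gamma.

No SVM solver ships with the allowed dependency set, so the package
implements the C-SVM dual with an SMO solver (maximal-violating-pair
working-set selection, analytic two-variable updates, per-sample box bounds
implementing balanced class weights). It reproduces a reference
implementation's decision values on a frozen fixture to ~1e-3.

The published evaluation -- "on the test dataset via five-fold stratified CV
repeated 100 times" -- is internally ambiguous (cross-validation *on* a
held-out set). Both readings are computed and reported side by side: a
single 80:20 hold-out evaluation, and repeated stratified 5-fold CV over the
full dataset with scaling refitted inside every fold. Threshold metrics
(sensitivity, specificity, PPV, NPV, balanced accuracy) use the margin
(score 0) as decision threshold; folds with undefined PPV/NPV are excluded
from those averages. AUC is rank-based and threshold-free. All randomness
derives from one master seed through tagged seed derivation
(`derive_seed`), so reports are bit-reproducible.

# Shapley attributions

`shap_contributions` uses the interventional coalition value: features
outside a coalition are replaced by background rows (default: the training
rows) and predictions averaged. With p <= 12 features all 2^p coalitions
are enumerated and the Shapley formula is exact, so local accuracy
(base + sum of contributions = model output) holds to machine precision;
with more features a seeded kernel-weighted regression over sampled
coalitions is used with the efficiency constraint eliminated into the
solver, so the identity still holds exactly. Contributions are computed on
decision scores, not thresholded labels, for stability. Dummy and symmetry
axioms are spot-checked in the test suite on constructed models.

One practical consequence of within-mask z-scoring is worth knowing: a
localized group increase in a raw metric necessarily *lowers* the
standardized values everywhere else (z-scoring is zero-sum across the
mask), so strong injected effects can produce small, genuine clusters of
the opposite sign elsewhere. The end-to-end tests therefore score recovery
by the best-overlapping cluster rather than demanding a unique one.

# Numerical choices and degenerate inputs

* Fisher z clips |r| at 1 - 1e-7 (warning) instead of overflowing.
* Zero-variance voxels are excluded from correlation metrics (DC/FCS treat
  them as uncorrelated; scaling maps them to zero columns).
* All-zero series get fALFF 0 with a warning; constant neighborhoods get
  ReHo 0 with a warning.
* Rank-deficient nuisance designs drop dependent columns with a warning;
  collinear GLM designs are an error naming the columns.
* Zero-range features rescale to 0 with a warning.
* `eta <= 0` SMO pairs (duplicate points) are guarded by a 1e-12 floor.

# Known limitations

* No NIfTI I/O: the allowed R dependency set contains no NIfTI package and
  hand-rolling the binary format was out of scope. Volumes live as R arrays
  with grid metadata; plain-text interchange (`write_cohort`) is provided.
* The GRF formulas use the Gaussianized-t approximation common to the
  standard toolboxes; at very low df it is conservative/anticonservative in
  the usual ways, which is why calibration is tested by simulation.
* The published headline classification numbers (e.g. AUC 100% for degree
  centrality) depend on undeposited patient scans and are out of reach by
  design; the package demonstrates the method's mechanics on stated
  synthetic ground truth instead.
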