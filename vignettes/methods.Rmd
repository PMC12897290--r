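---
title: "Leakage-controlled classification of task-fMRI activation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leakage-controlled classification of task-fMRI activation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`fmricv` implements a complete, testable analysis chain for discriminating
patient groups from healthy controls (HC) using task-evoked BOLD
activation, in the setting of an emotional Go/NoGo paradigm acquired from
bipolar-disorder (BD) subgroups (remission, depression, mania) and matched
controls. Because clinical BOLD data of this kind cannot be shared, the
package ships a first-class synthetic-data generator with known ground
truth, and every downstream claim the package makes is validated against
that ground truth. The chain is:

1. **simulation** of 4D BOLD cohorts with group effects planted in known
   atlas regions;
2. **preprocessing**: framewise-displacement (FD) motion QC, scrubbing,
   Friston-24 + WM/CSF + trend nuisance regression, 0.01–0.10 Hz band-pass,
   4 mm Gaussian smoothing;
3. **GLM**: per-subject contrast z-maps for six task conditions, and
   two-sample group z-maps;
4. **random-field theory (RFT)**: two-sided Gaussian-random-field cluster
   correction (voxel p < 0.001, cluster p < 0.05, minimum extent 10);
5. **features**: fold-internal "abnormal ROI" definition and leakage-free
   vectorized ROI time-series features;
6. **classification**: nested stratified cross-validation (outer 5-fold,
   inner 3-fold grid search) over five classifier families, pooled
   out-of-fold metrics, 10,000-resample bootstrap intervals;
7. **explanation**: held-out Shapley attributions aggregated to ROI-level
   importance shares;
8. **clinical association**: voxelwise brain–behavior regression, GRF
   correction, per-cluster standardized coefficients, Benjamini–Hochberg
   FDR within each contrast/mood-state/group block.

# The synthetic cohort

`sim_config()` fixes the emulated acquisition: TR = 2 s, 307 usable
volumes, 3 mm isotropic voxels, three HRF-convolved face conditions (Go =
happy, NoGo = sad, Neutral), and the cohort composition 15 remission / 11
depression / 17 mania / 43 HC (`default_group_sizes()`). The spatial grid
defaults to 24 × 24 × 18 voxels carrying 12 regions — a deliberately small
stand-in for a whole-brain parcellation that keeps every experiment
runnable on a laptop; all analyses are grid-size agnostic.

Per subject the BOLD signal is

$$y_v(t) = 100 + \sum_c a_{r(v),c,g}\, x_c(t) + \varepsilon_v(t),$$

where $x_c$ is the condition-$c$ boxcar convolved with the canonical
double-gamma HRF (response peak near 6 s, undershoot near 16 s, 1/6
relative amplitude, peak-normalized so amplitudes read as percent signal
change over the baseline of 100), and $a_{r,c,g}$ is the amplitude of
region $r$, condition $c$, group $g$. The BD − HC difference
(`effect_size`, percent signal) is added to the **Go** amplitude inside
`effect_rois` only, so the Go − NoGo contrast carries the group effect and
all other regions are exact nulls. A subject-level amplitude jitter
(`subject_amp_sd`) makes activation a random variable across subjects;
planted clinical links draw the named score as
$\rho\, z_a + \sqrt{1-\rho^2}\,\epsilon$ from the subject's standardized
jitter $z_a$, so the population correlation between regional activation
and the score is exactly $\rho$ and the association analysis has a
recoverable target.

Noise is AR(1) in time per voxel (lag-1 coefficient `ar_coeff`, default
0.3) with the innovation variance set so the marginal SD equals
`noise_sd`; each frame of the innovation field is Gaussian-smoothed
(`spatial_fwhm_mm`, default 6 mm) and rescaled back to the marginal SD, so
the noise has realistic spatial smoothness for RESEL estimation while
`noise_sd` stays interpretable. Motion traces are smooth random-walk
drifts (≈0.002 mm / 2×10⁻⁵ rad per step) plus single-volume spikes of
0.4–0.9 mm with per-volume probability `motion_spike_prob`.

What the generator does **not** emulate: physiological noise structure
(cardiac/respiratory), susceptibility artifacts, motion-correlated signal
(motion and BOLD are independent), inter-subject anatomical variability
(all subjects share one grid, so spatial normalization is out of scope),
and scanner drift beyond a linear trend. Passing tests therefore
demonstrate the statistical machinery is correct and leak-free, not that
real BD cohorts are this separable.

The event schedule is pseudo-randomized once from the configuration seed
and reused for every subject — trial sequence and timing identical across
subjects, as in the emulated task — with jittered inter-trial intervals on
a 0.1 s grid, so onsets do not align with volume boundaries and the
micro-time HRF convolution is exercised.

# Preprocessing decisions

* **FD (Jenkinson)**: RMS displacement of the rigid transform difference
  over a sphere of radius 80 mm (the method's canonical constant) centered
  at the volume center, with rotations taken about that center:
  $FD_t = \sqrt{R^2/5 \cdot \mathrm{tr}(A^\top A) + b^\top b}$. Exclusion
  uses strict thresholds (translation > 3 mm, rotation > 3°); scrubbing
  flags FD > 0.2 mm and absorbs those volumes with one-hot spike
  regressors rather than deletion, so all subjects keep a common time-axis
  length (ROI series lengths differ only if volume deletion is introduced
  upstream; the `t_use` truncation rule handles either case).
* **Nuisance model**: Friston-24 (parameters, squares, one-volume lags,
  squared lags, lag at the first volume set to 0), WM and CSF compartment
  means (taken from designated background planes of the toy atlas), a
  standardized linear trend, and the spike columns. Rank-deficient designs
  (e.g., an all-zero motion trace) are handled by pivoted least squares
  with an explicit warning, never silently.
* **Order of operations**: nuisance regression → band-pass → smoothing,
  following the order the emulated protocol lists. Band-passing task data
  before the GLM is unusual for task fMRI (it attenuates task variance
  outside the band); it is implemented as stated and flagged here as a
  property of the emulated protocol, not a recommendation.
* **Band-pass**: hard frequency-domain masking of 0.01–0.10 Hz on the
  residualized series, with the voxel mean restored afterwards. This is
  deterministic, exactly idempotent, and trivially characterizable (the
  tests measure the empirical frequency response).
* **Smoothing**: separable Gaussian via circular FFT convolution. Circular
  convolution conserves each frame's mean exactly and has unit DC gain;
  the wrap-around at grid faces is harmless on synthetic grids whose shell
  is background. FWHM is converted to voxels through the configured voxel
  size (4 mm on 3 mm voxels ≈ 1.33 voxels).

# GLM and t→z conversion

First-level: ordinary least squares per voxel on the HRF-convolved
condition regressors plus intercept, with the contrast t statistic
converted to z through the probability integral transform using log-space
tail probabilities, which keeps |z| finite and accurate for |t| up to
machine range. Zero-residual-variance voxels (possible on degenerate
synthetic input) are set to z = 0 and counted. The six contrast weight
vectors over (Go, NoGo, Neutral) are fixed: Go−NoGo = (1,−1,0),
Go+NoGo = (1,1,0), Go−Neutral = (1,0,−1), NoGo−Neutral = (0,1,−1),
Go = (1,0,0), NoGo = (0,1,0); scaling a contrast does not change z, so
(1,1,0) is used for the combined condition. Contrasts are estimated
directly from their weight vectors, never as differences of z-maps.

No AR(1) prewhitening is applied at the first level: the preprocessing
chain has already reshaped the noise spectrum (band-pass), and the
within-subject df only enters the t→z transform. This is a documented
limitation; group-level inference rests on the between-subject second
level, which is unaffected.

Second-level: voxelwise two-sample pooled-variance comparison (equivalent
to a group-indicator GLM), sign convention patients − controls, df =
nA + nB − 2, with the per-subject residual maps retained for smoothness
estimation.

# Random-field cluster correction

Smoothness is estimated Kiebel-style from standardized residual maps: the
per-axis mean squared first difference estimates the derivative variance
λ, and FWHM = √(4 ln 2 / λ) per axis; RESELs = masked voxels / ∏ FWHM.
For white noise this estimator returns ≈1.18 voxels (the theoretical
lattice value), and it recovers an applied Gaussian kernel's FWHM to
within a few percent at kernel widths ≥ 2 voxels.

Cluster formation uses the two-sided threshold u = Φ⁻¹(1 − p/2) applied
separately to the positive and negative excursions, with components
defined under **18-connectivity** (faces + edges — the SPM-family
convention; corner-contact does not connect). Per cluster the corrected p
follows the classic 3D approximation: expected cluster count from the
Euler-characteristic density
ρ₃(u) = (4 ln 2)^{3/2} (2π)^{-2} (u²−1) e^{−u²/2} times the RESEL count,
expected suprathreshold volume S·Φ(−u), and extent tail
P(n ≥ k) = exp(−β k^{2/3}) with β = (Γ(5/2)·E[m]/E[N])^{2/3}. The
two-sided α is split evenly across tails at both voxel and cluster level.
Retention requires corrected p < α/2 per tail **and** extent ≥ 10 voxels.
A Monte-Carlo validator (500 simulated null fields of known smoothness)
lives in the test suite, not in the pipeline; at FWHM 3 voxels the
empirical family-wise rate is ≈0.04. Below ≈2.5 voxels FWHM the continuous
approximation grows conservative on a lattice — a known property, which is
why the calibration experiment fixes 3 voxels.

# Fold-internal features and the leakage contract

Within each outer fold, using TRAIN subjects only: a patients-vs-controls
second-level z-map, GRF correction, intersection of the surviving mask
with the atlas, and retention of regions overlapping by ≥10 voxels yields
the fold's K abnormal ROIs (ascending label order). ROI-mean time series
(over the mask-intersected voxel sets) are truncated to
t_use = min over TRAIN subjects' lengths, vectorized **ROI-major** (all
t_use time points of ROI 1, then ROI 2, …; the order is recorded in an
index map so Shapley aggregation is well defined), and z-standardized per
column with center/scale fitted on TRAIN rows only. TEST subjects are
truncated and scaled with the TRAIN parameters; a TEST subject shorter
than t_use is an error, never silent padding. K = 0 folds are skipped and
counted. The test suite asserts the whole contract mechanically: perturbing
any TEST subject's data changes neither the ROI set, nor t_use, nor the
scaler.

# Classification

Outer 5-fold / inner 3-fold stratified CV (round-robin assignment of each
class's shuffled members, so fold class ratios differ by at most one
subject), reproducible from a single seed. The inner grid search maximizes
pooled inner out-of-fold AUC; ties resolve to the first grid entry. The
five families and their default grids (all config, not fidelity claims,
since the emulated protocol's grids are not public): ridge logistic
regression (λ ∈ {0.01, 0.1, 1}), linear SVM (cost ∈ {0.1, 1, 10}), random
forest (mtry fraction ∈ {0.1, 0.33}, 200 trees), gradient-boosted trees
(depth ∈ {2, 3}, η ∈ {0.1, 0.3}, 40 rounds), Gaussian naive Bayes (no
tuned parameter). Scores are class-1 probabilities except the SVM, which
uses its decision value; confusion matrices threshold at 0.5 / 0 with no
threshold tuning. Metrics (accuracy, sensitivity, specificity, AUC, F1,
PPV, NPV, FDR = 1 − PPV) come from the pooled out-of-fold predictions;
AUC is the rank statistic. 95% intervals are percentile bootstrap over
10,000 subject-level resamples of the pooled predictions, excluding (and
counting) one-class resamples for AUC.

One caveat the null experiments surface: pooling scores across folds with
differing calibration can push the null AUC slightly below 50% for poorly
calibrated scorers (naive Bayes especially). This is a property of pooled
out-of-fold AUC itself, not leakage; the leakage experiment's acceptance
band (40–60% over 20 seeds) accommodates it.

# Shapley-based ROI importance

Per fold, attributions are computed on the held-out TEST rows with an
explainer matched to the model: exact tree-path SHAP for the boosted
trees, the closed-form linear attribution β·(x − x̄_train) for the ridge
logistic model, and a permutation-sampling Shapley estimator against the
TRAIN-mean baseline for the other families. With a single baseline each
sampled permutation telescopes exactly, so per-subject attributions sum to
f(x) − f(baseline) identically (the tests assert this to machine
precision). Column attribution magnitudes are summed within each ROI over
its time-point columns, normalized to within-fold shares (preventing
high-magnitude folds from dominating), averaged across the folds where
the ROI was selected, and reported with a folds-present count; the ROI
sets may differ across folds, so the averaged shares are renormalized to
sum to 100% over the ROIs present. Ranking depends only on the index map,
not on the vectorization order.

# Clinical association

For each contrast/mood-state/group block, fit separately per group (no
pooled model exists in the code path): per metric, a voxelwise simple
regression of the subjects' contrast maps on the metric (intercept +
slope only — the design has exactly two columns, no covariate
adjustment), slope t → z, GRF correction with smoothness from the
regression residuals, subject-level cluster means for surviving clusters,
and a standardized simple regression per (cluster, metric) — both
variables z-scored, so the standardized coefficient equals the Pearson
correlation and |β| ≤ 1. Raw p and BH-FDR q (computed within the block
via the step-up procedure; q ≥ p, monotone in p) are always reported
together; discovery means q < 0.05. Anatomical labels are the
majority-overlap atlas region per cluster.

Recovered β values are mildly attenuated relative to the planted
correlation because the cluster mean estimates regional activation with
first-level noise; at the problem sizes used in the validation experiments
(n = 30, 150 volumes, amplitude SD 1.5% against noise SD 0.8%) the
attenuation is ≈0.9, which the recovery experiment's ±0.15 band absorbs.

# Determinism and problem sizes

A single integer seed governs everything: cohort, fold plan, classifier
fitting, bootstrap, and Shapley sampling, each through a documented
seed-derivation (`derive_seed(seed, tag)`). Two runs with identical config
and seed produce byte-identical result tables, including the bootstrap
intervals.

The validation experiments run at deliberately small scale so the whole
suite executes in minutes: grids of 14³–24³ voxels, 60–150 volumes,
cohorts of 16–30 subjects, 400–500 Monte-Carlo null fields, 5–20 seeds
per experiment. These sizes are the package's chosen study conditions for
its own validation; every analysis function is size-agnostic and runs
unchanged at full acquisition scale (307 volumes, larger grids, 43 + 43
subjects).

# Known limitations

* The GRF extent approximation is the classic closed form; no permutation
  alternative is provided in the main path (a Monte-Carlo validator ships
  in the tests).
* First-level inference ignores serial correlation left after band-pass
  (no prewhitening); group inference is between-subject and unaffected.
* Circular smoothing wraps at grid faces; irrelevant for the synthetic
  shell-padded grids, but real data near field-of-view edges would need
  renormalized truncated kernels.
* The simulator's nulls are exactly exchangeable; real resting motion,
  physiology and site effects are not represented, so classification
  results on synthetic cohorts bound what the pipeline can do only in the
  statistical sense (no leakage, correct calibration), not clinically.
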