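# fmricv

Leakage-controlled classification of task-fMRI activation patterns, with
a ground-truth synthetic cohort generator.

## The problem

Task-fMRI studies of psychiatric cohorts — here, adolescents with bipolar
disorder (BD) in remission, depression or mania versus matched healthy
controls (HC) performing an emotional Go/NoGo task — often build machine
learning classifiers on features derived from group statistics
(“abnormal” regions found by contrasting patients with controls). Done
naively, that feature definition sees the test subjects and the reported
accuracy is circular. `fmricv` implements the analysis the right way and
makes the leakage contract mechanically testable:

* **Preprocessing**: Jenkinson framewise displacement, gross-motion
  exclusion (>3 mm / >3°), scrubbing (FD > 0.2 mm) with spike regressors,
  Friston-24 + WM/CSF + linear-trend nuisance regression, 0.01–0.10 Hz
  band-pass, 4 mm Gaussian smoothing.
* **GLM**: per-subject contrast z-maps for six conditions over
  (Go, NoGo, Neutral) — Go−NoGo, Go+NoGo, Go−Neutral, NoGo−Neutral, Go,
  NoGo — and two-sample group z-maps,
  t = c′β̂ / √(σ̂² c′(X′X)⁻¹c) converted to z through the t CDF.
* **GRF cluster correction**: two-sided, voxel p < 0.001, cluster
  p < 0.05, minimum extent 10 voxels, 18-connectivity, with Kiebel-style
  smoothness estimation (FWHM = √(4 ln 2/λ)) and the classic 3D
  cluster-extent tail P(n ≥ k) = exp(−β k^{2/3}).
* **Fold-internal features**: per outer CV fold, abnormal ROIs are defined
  from TRAIN subjects only (mask ∩ atlas, overlap ≥ 10 voxels), ROI-mean
  time series truncated to t_use = min over TRAIN lengths, vectorized to
  a 1 × (t_use·K) feature vector, scaled with TRAIN-fitted parameters.
* **Nested CV**: outer 5-fold / inner 3-fold stratified grid search over
  logistic regression, SVM, random forest, gradient-boosted trees and
  naive Bayes; pooled out-of-fold accuracy/sensitivity/specificity/AUC/
  F1/PPV/NPV/FDR; 95% percentile bootstrap CIs from 10,000 resamples.
* **Explanation**: held-out SHAP per fold (tree-path, linear, or
  permutation-sampling explainer by family) aggregated to ROI importance
  shares.
* **Clinical association**: voxelwise regression of activation on
  behavioral/clinical scores, GRF correction, per-cluster standardized β
  (= Pearson r), Benjamini–Hochberg FDR within each
  contrast/mood-state/group block.

Because real cohorts of this kind are not shareable, the `sim_config()` /
`simulate_cohort()` generator produces 4D BOLD cohorts (TR 2 s, 307
volumes, 3 mm voxels by default; HRF-convolved face conditions; spatially
smooth AR(1) noise; motion spikes; default group sizes 15/11/17 BD + 43
HC) with effects planted in known regions and clinical scores linked to
activation at a known correlation — so recovery, calibration and leakage
are all checkable against ground truth.

## Worked example

```r
library(fmricv)

cfg <- sim_config(grid_shape = c(16, 16, 12), n_volumes = 80, n_regions = 6,
                  n_events_per_condition = 8,
                  effect_rois = c("region_01", "region_04"),
                  effect_size = 3, seed = 42)
cohort <- simulate_cohort(cfg, c(remission = 10, HC = 10))
cohort
#> <fmri_cohort> HC=10, remission=10

prep <- prepare_cohort(cohort, contrasts = "go_minus_nogo")
labels <- setNames(as.integer(prep$groups == "remission"), prep$ids)
plan <- make_fold_plan(labels, seed = derive_seed(42, "folds"))
reports <- run_nested_cv(prep, "go_minus_nogo", labels, plan,
                         classifier_spec("rf"), compute_shap = TRUE, seed = 42)
summary(reports$rf)
#> <evaluation_report> go_minus_nogo / rf: accuracy 100.00%, sensitivity 100.00%, specificity 100.00%, AUC 100.00%, F1 100.00%
#>   95% CI: AUC [1.000, 1.000], accuracy [1.000, 1.000] (10000 resamples, 0 one-class excluded)
#> <importance_table> ROI importance (share of |SHAP| mass, %)
#>        roi share mean_abs_shap folds_present
#>  region_04  52.2         0.267             5
#>  region_01  47.8         0.244             5
```

A 3% planted Go-amplitude difference against 1% noise is trivially
separable — the point of the example is what surrounds the number: the
ROI set driving the classifier was re-derived inside every training fold
(never from test subjects), and the SHAP importance table ranks exactly
the two regions the generator injected, with the fold count showing they
were selected in all five folds. On a null cohort (`effect_size = 0`) the
same pipeline returns chance-level out-of-fold AUC — that experiment, and
the calibration of every statistical component, runs in the test suite.

Higher-level drivers wrap the same machinery: `run_state_specific()`
(one mood state vs HC, six contrasts × five classifiers) and
`run_pooled_generalization()` (ROIs from one state's TRAIN subjects,
evaluation on pooled BD vs HC), both writing result tables and a
reproducibility manifest. `clinical_association()` produces the
brain–behavior table (cluster, size, label, metric, β, p, q).

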