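# physiomot

Physio-motor biomarkers of Rett syndrome severity from wearable
signals.

Rett syndrome severity is rated clinically on the 7-point CGI-S scale.
`physiomot` derives objective correlates of that rating from two-day
wearable recordings — ECG-derived RR intervals and three-axis
acceleration — which in home use are heavily gappy (device charging,
motion artifacts, compliance). The package implements the full analysis
chain:

* **Missing data**: per-window multi-channel ECG fusion by signal
  quality index (best channel kept iff SQI > 0.75), shape-preserving
  (PCHIP) hourly activity imputation, and a stochastic surrogate
  imputation that fills each gap with a same-length donor segment chosen
  by a coin flip and a folded-normal offset, plus 5% Gaussian noise —
  repeated to build 100-member ensembles per visit.
* **Features**: 48 nocturnal HRV features (mean/variance of 24 windowed
  metrics including phase-rectified deceleration capacity,
  DC = (X(0) + X(1) − X(−1) − X(−2))/4 over phase-aligned anchors);
  8 actigraphy features from Oakley activity counts (IS, IV, L5, M10,
  relative amplitude, and cosinor mesor/amplitude/acrophase); 120
  multiscale transfer-entropy features,
  TE(X→Y) = H(y_i | y_{i−1}) − H(y_i | y_{i−1}, x_{i−1}) in nats,
  estimated by Darbellay–Vajda adaptive partitioning over six directed
  pairs of (HR, DC, activity) at coarse-graining scales 1–10; and 220
  multiscale transition-network features (node/degree/cycle/clustering/
  radius/spectral metrics at each scale). Ensemble means and variances
  summarise the surrogate distribution.
* **Classification**: CGI-S binarised at 4; all 15 feature-family
  combinations fitted with L1-penalised logistic regression under
  leave-one-patient-out cross-validation (inner 3-fold penalty tuning,
  5 repetitions, median-pooled probabilities), scored by pooled
  rank-based AUC, with feature popularity ρ = (#models with non-zero
  coefficient)/#models.
* **Synthetic cohorts**: a generator with circadian structure,
  directional activity→HR coupling, severity-linked deceleration
  capacity, per-channel SQI traces and realistic wear gaps, plus a
  closed-form Gaussian VAR(1) transfer-entropy oracle
  (`analytic_te_var1()`) for estimator validation.

## Worked example

```r
library(physiomot)

coh <- generate_cohort(cohort_config(n_patients = 6, master_seed = 29))
cfg <- pipeline_config(cohort = coh, ensemble_m = 2,
                       hrv_metrics = c("NNmean", "SDNN", "RMSSD",
                                       "PNN50", "PRSA_AC", "PRSA_DC"),
                       master_seed = 29)
res <- run_pipeline(cfg)
res$features
#> <feature_table> 10 visits x 360 features (ACT:8 HRV:12 MSNR:220 MSTE:120), 6 patients
res$experiment
#> <full_experiment> pooled AUC by feature combination:
#>        combination pooled_auc n_models
#>                HRV       0.96       30
#>                ACT       0.44       30
#>               MSTE       0.40       30
#>               MSNR       0.40       30
#>            HRV+ACT       0.96       30
#>           HRV+MSTE       0.96       30
#>           HRV+MSNR       0.80       30
#>           ACT+MSTE       0.44       30
#>           ACT+MSNR       0.48       30
#>          MSTE+MSNR       0.40       30
#>       HRV+ACT+MSTE       0.88       30
#>       HRV+ACT+MSNR       0.84       30
#>      HRV+MSTE+MSNR       0.92       30
#>      ACT+MSTE+MSNR       0.28       30
#>  HRV+ACT+MSTE+MSNR       0.88       30
```

This small demonstration cohort (6 patients, 10 visits, 2 surrogate
members, reduced HRV metric set) separates by severity through the HRV
features: combinations containing HRV reach pooled AUCs of 0.8–0.96,
while activity-only and network-only models hover near chance. Each row
pools the held-out probabilities of 5 repetitions × 6 patient folds
(n_models = 30). `res$experiment$top_popularity` lists, per combination,
which features the LASSO kept: here the phase-rectified capacity
features dominate, as the generator links severity to deceleration
capacity. At full scale (`ensemble_m = 100`, all 24 HRV metrics) each
visit carries 48 + 8 + 120 + 220 = 396 features.

Cohorts round-trip through plain CSV directories with `write_cohort()` /
`read_cohort_dir()`, so the pipeline also runs from files.

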