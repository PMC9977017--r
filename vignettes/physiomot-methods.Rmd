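---
title: "Methods: physio-motor severity biomarkers from wearable signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physio-motor severity biomarkers from wearable signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Rett syndrome severity is scored clinically on the 7-point CGI-S scale.
`physiomot` derives objective physio-motor correlates of that score from
two-day wearable recordings: ECG-derived RR intervals and three-axis
acceleration, both heavily gappy in home use (device charging, motion
artifacts, compliance). The pipeline runs from raw gappy signals to an
L1-penalised severity classifier and a feature-popularity ranking, and a
synthetic cohort generator provides ground truth for end-to-end
validation, since the clinical recordings that motivated the design are
not public.

# Missing-data handling

Three imputation stages, in pipeline order:

* **SQI-based channel fusion** (`fuse_channels_by_sqi()`): for each
  60-second window, the ECG channel with the highest signal-quality
  index is kept if and only if its SQI strictly exceeds 0.75; otherwise
  the window is discarded and becomes a gap. Ties go to the lowest
  channel id so that fusion is deterministic. `simple_bsqi()` provides a
  deliberately simple SQI — the agreement fraction of two dissimilar
  beat detectors (a conservative amplitude detector and a sensitive
  slope-energy detector, matched within ±150 ms). The dissimilar noise
  responses are what make the score collapse on corrupted windows while
  staying at 1.0 on clean signal.
* **Hourly PCHIP imputation** (`pchip_impute_hourly()`): activity counts
  are summed per clock hour; empty interior hours are filled by
  shape-preserving piecewise-cubic interpolation (no overshoot between
  neighbouring hours), leading/trailing empty hours by nearest-hour
  values (PCHIP is an interior interpolant; edges are flagged).
* **Stochastic surrogate imputation** (`surrogate_impute()`): gaps
  longer than `th_g` are filled, shortest first, by copying a same-length
  donor segment from the gap's neighbourhood. A fair coin picks the
  side; a folded-normal draw `|x_r|` (x_r ~ N(0,1)) sets the donor
  offset `|x_r| * g_l` seconds beyond the admissible boundary, so the
  search neighbourhood scales with gap length and the donor never
  overlaps the exclusion zone (`t < t_b - g_l` on the left, `t > t_e` on
  the right). Additive noise `0.05 * z`, `z ~ N(mu_S, sigma_S^2)` with
  the moments of the pre-imputation series, is applied per copied
  sample. Because the series is updated after each gap, already-imputed
  short gaps can donate to longer ones. Repeating the procedure with
  member seeds `base_seed + i` yields the 100-member ensembles used for
  the coupling features.

Defaults that the sources leave open and that we pinned: `th_g` = 60 s
for the 30-s HR/DC/activity grids and 300 s for raw RR; donor-offset
redraws capped at 50 per side; noise read as additive (an alternative
reading — noise proportional to each sample — would change variance
properties and is not implemented).

# Feature families

**HRV (48 features).** RR artefacts are removed (intervals outside
300–2000 ms, or changing > 20% from the last accepted beat). Metrics are
computed in 300-s windows shifted by 30 s; a window is valid with ≥ 80%
beat-time coverage and ≥ 30 beats. The 24-metric set covers time-domain
(NNmean, NNmedian, NNmode, NNvariance, NNskew, NNkurt, NNiqr, SDNN,
RMSSD, PNN50, meanHR), Lomb–Scargle band powers on the irregular beat
times (ULF ≤ 0.003 Hz, VLF, LF, HF ≤ 0.4 Hz, LF/HF, total), entropies
(SampEn, ApEn; m = 2, r = 0.2 sd), PRSA capacities (AC, DC; anchor
filter 5%, half-window L = 30 beats, Bauer four-point estimate), and
DFA slopes plus the Poincaré SD1/SD2 ratio. Each metric contributes its
sample mean and sample (n−1) variance over windows starting in the
half-open nocturnal interval [22:00, 10:00) of either night: 48
features. Windows are assigned by start time so boundary behaviour is
deterministic.

**Actigraphy (8 features).** Acceleration is converted to counts by the
Oakley scheme (0.25 Hz high-pass, per-second maximum absolute
deviation, 0.05 g deadband, per-epoch sum); the constants are pinned
since only the method family is standard. The best two consecutive
midnight-to-midnight days (most non-missing hours, earliest pair on
ties) must both carry ≥ 12 h of data, else the visit is rejected. On the
48 PCHIP-completed hourly values we compute interdaily stability,
intradaily variability, L5, M10, the relative amplitude
RA = (M10 − L5)/(M10 + L5) — our reading of the "rest activity"
summary — and the cosinor mesor, amplitude and acrophase (least squares
through the linear cos/sin parameterisation; amplitude non-negative,
acrophase in [0, 24) h, pinned to 0 with a flag for flat fits).

**Multiscale transfer entropy (120 features).** The HR, DC and activity
signals live on a common 30-s grid (nominally 5760 points for 48 h); DC
is the PRSA deceleration capacity of a 300-s window centred on each grid
point. Signals are coarse-grained at scales 1–10 (non-overlapping
means; scale 10 is one sample per 5 minutes). Transfer entropy uses
block lengths and lags of one: triples `(y_i, y_{i-1}, x_{i-1})` are
rank-normalised and partitioned by the Darbellay–Vajda scheme —
recursive midpoint splits of rank intervals, accepted when the cell
holds ≥ `min_cell * 2^d` points and the chi-square uniformity statistic
exceeds the `chisq(2^d − 1)` critical value at alpha = 0.05 — and the
plug-in conditional mutual information is summed over leaves with
marginal counts from each leaf's projected rank ranges. Entropy is in
nats. Rank normalisation makes the estimator exactly invariant under
strictly monotone transforms; the projected-marginal plug-in can go
slightly negative (tests allow −0.01). Heavy ties (e.g. constant
signals) get seeded random rank jitter, since index-based tie-breaking
would fabricate a perfect diagonal dependence. The six directed pairs
(HR→DC, HR→Act, DC→Act, DC→HR, Act→HR, Act→DC) at ten scales, summarised
by ensemble mean and variance over the 100 surrogate members, give 120
features.

**Multiscale network representation (220 features).** At each scale the
three coarse-grained signals form a 3-D point cloud, partitioned the
same way; occupied leaves are nodes, consecutive time points in
different cells add an undirected edge, and a repeated cell marks a
self-loop. The sources do not state how cells become a network; the
undirected consecutive-transition rule is the standard transition-network
construction and our pinned choice. Eleven metrics per scale: node
count, average degree (self-loops excluded from degree), cyclomatic
number |E| − |V| + components, 3- and 4-cycle counts (trace formulas,
validated against exhaustive enumeration), LOOP3/connected-triples
(implemented exactly as defined, without the conventional factor 3,
which is available behind `transitivity_factor3`), mean local
clustering, graph radius on the largest component, and the spectral
triple — spectral radius, trace, and energy as the *sum of squared*
eigenvalues (the definition used here; note it differs from the common
graph-energy convention of summed absolute eigenvalues). Self-loops
enter the adjacency diagonal, so the trace counts self-loop nodes
rather than being identically zero. Ensemble mean and variance over
members give 220 features.

# Severity classification

CGI-S ≤ 4 is low severity, > 4 high. All 15 non-empty family subsets are
fitted with L1-penalised logistic regression (`glmnet`), evaluated by
leave-one-patient-out cross-validation: all visits of one patient are
held out together, features are z-scored on the training rows only, and
the penalty is chosen from a 50-value log-spaced grid spanning
`[lambda_max, 1e-4 lambda_max]` by an inner 3-fold CV over training
patients, stratified by patient-level label. The experiment is repeated
five times with reshuffled inner folds; each visit's pooled probability
is the median over repetitions and the pooled AUC is computed once,
rank-based with half credit for ties. Feature popularity is the
fraction of the 5 × #patients models in which a feature's coefficient is
non-zero, reported with competition ranking (ties share a rank).

Two design choices here were genuinely open and deserve their
rationale:

* **Balanced class weights in every fit.** Without them the null
  model's intercept equals the training class log-odds — which, in
  leave-one-patient-out CV, is determined by the held-out patient's own
  class. Pooling such probabilities ranks every held-out patient by its
  own label, inverted: a structural leak that drives the pooled AUC of
  label-free data toward 0 rather than 0.5. Balanced weights pin the
  null-model probability at 0.5 for every fold.
* **Penalty selection by held-out deviance with the one-SE rule.** A
  rank-based criterion (inner AUC) is piecewise constant along the
  penalty path, so any tie-breaking rule degenerates: choosing the
  sparsest tied penalty yields near-constant probabilities that pool
  poorly across folds; choosing the least sparse one overfits on
  uninformative folds. Binomial deviance is smooth in the penalty, and
  the one-SE rule (largest penalty within one standard error of the
  minimum, with the all-zero model as the fallback benchmark) returns
  the null model on uninformative folds and a confident, useful fit
  when signal is present.

Even so, a minority of label-free cohorts shows pooled AUC well below
0.5. This is the known anti-learning bias of leave-one-out schemes at
small n: a chance patient-level association that happens to hold
cohort-wide minus-one is selected in every fold, and the held-out
patients fall systematically on its wrong side. It is a property of the
evaluation scheme, not an implementation artifact; the null-behaviour
tests document it quantitatively.

# The synthetic cohort generator

The generator (`generate_cohort()`) emulates the study conditions:
20 patients, one or two visits each (about 32 visits in expectation),
48-h recordings on a 30-s latent grid, CGI-S 2–4 in the low-severity
group and 5–7 in the high-severity group. Per visit:

* activity follows a 24-h cosinor (default acrophase 15 h, amplitude 20
  counts) plus AR(1) noise, clipped at zero;
* latent HR follows `hr_t = a hr_{t-1} + gamma act_dev_{t-1} +
  circadian + noise` (a = 0.6), so activity drives HR and not vice
  versa — the direction the transfer-entropy features should recover.
  The coupling coefficient gamma has equal group means but
  group-specific variance;
* beats are produced by rate inversion of the HR grid with 3%
  multiplicative AR jitter, and RR is rebuilt as the cumulative sum so
  beat times and intervals stay consistent;
* deceleration episodes — a sharp two-beat RR lengthening (25 ms) with
  a gradual four-beat recovery — occur at `0.7 * dc_mean` per minute.
  The asymmetric, small-step shape is deliberate: phase-rectified DC
  responds linearly to the per-beat step while RMSSD and PNN50 respond
  quadratically, and the slow recovery keeps acceleration capacity from
  mirroring DC, so `dc_mean` moves deceleration capacity specifically,
  which is the biomarker structure the analysis is designed to detect.
  High-severity visits have `dc_mean` lower by `dc_effect` (default
  4 ms; within-group SD 0.5 ms);
* per-60-s, per-channel SQI traces are Beta-distributed with a mean
  that degrades with activity (0.95 − 0.18 × normalised activity,
  concentration 60), so single channels lose daytime windows while the
  best-of-N fusion retains almost all of them;
* wear gaps — one ~2-h charging gap per day plus exponential dropouts
  (0.5/h, mean 120 s) — are applied jointly to RR and counts, as the
  device is off for both.

Everything is a pure function of the master seed through a counter-based
seed fan-out, so cohorts are reproducible and member/visit streams
independent.

What the generator does *not* emulate: ECG waveform morphology,
breathing, sleep-stage structure, artefact bursts correlated across
channels, and patient-level traits persisting across visits (visit
parameters are drawn independently per visit). Passing tests therefore
show that the pipeline recovers the statistical structure it assumes —
directional coupling, circadian rhythm, severity-linked deceleration
capacity — not that it would reach any particular performance on real
recordings.

# Validation design and problem sizes

The test-suite validation uses these sizes, chosen to exercise the
pipeline at the study's scale where it matters and smaller elsewhere:

* parameter recovery: 10 cohorts of 20 patients, one-or-two-visit
  structure, with `dc_effect = 2.9` ms — calibrated so the *measured*
  nocturnal deceleration-capacity feature separates the groups by about
  three pooled standard deviations (the tests verify the realized gap
  rather than assuming it). Classification uses the six-metric reduced
  HRV set (NNmean, SDNN, RMSSD, PNN50, PRSA_AC, PRSA_DC; 12 features
  with means and variances), which contains the deceleration-capacity
  biomarker and keeps ten-cohort runs tractable;
* null behaviour: 20 zero-effect cohorts of the same structure;
* oracle checks: transfer entropy vs the closed-form Gaussian VAR(1)
  value at n = 10^4 (20 seeds, ±20% on the median), exact cycle-count
  and L5/M10 equivalence, exact AUC pair-counting equivalence;
* structural layout: full 24-metric HRV on one complete visit (48
  features) and two-member ensembles for the 120/220-feature blocks,
  whose lengths do not depend on ensemble size; the 3200-series check
  uses the full 100-member ensembles on a 32-visit cohort.

`scripts/acceptance.R` recomputes the same quantities from scratch
against the installed package and writes them as JSON.

# Numerical choices and degenerate inputs

* Variances use the n−1 denominator throughout.
* PRSA needs a full ±L window per anchor; windows with too few beats
  shrink L rather than fail, and anchor-free windows (constant RR)
  report missing DC, which simply leaves a grid gap for the imputer.
* Lomb–Scargle band powers integrate a 2× oversampled frequency grid up
  to 0.4 Hz with phase-rotation recurrences; the absolute scale is a
  variance decomposition of the window, and only relative band
  structure matters downstream.
* Constant series: rest-activity IS/IV/RA and cosinor acrophase are
  undefined and reported missing/flagged, never silently zero —
  except acrophase, pinned to 0 with an explicit `flat` flag.
* Zero-variance feature columns are dropped per training fold; folds
  whose training data lose a class are skipped with a warning.
* Partition ranks use ties-by-index for ordinary data and seeded random
  jitter under heavy ties; the chi-square split test holds the type-I
  error of a uniform cell at alpha.

# Known limitations

* The SQI stand-in is a beat-agreement score, not the published
  multi-detector algorithm; it is pluggable by design.
* The transfer-entropy estimator is the adaptive-partition plug-in; KSG
  or other k-NN estimators are out of scope.
* The anti-learning tail of leave-one-patient-out pooling at n ≈ 32 is
  documented but not corrected; correcting it (e.g. leave-pair-out)
  would change the evaluation protocol this package implements.
* Actigraphy uses the z-axis only, and wear-time detection beyond the
  12-h rule is not attempted.
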