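# ppgbp

Detecting blood-pressure (BP) variation under hypovolemia from the
morphology of the photoplethysmography (PPG) pulse wave, recorded at a
constant external cuff pressure.

## Who this is for

Researchers in physiological signal processing and hemodynamic monitoring
who want a testable, end-to-end reference implementation of the
volume-compensation (vascular-unloading) approach to noninvasive BP-trend
surveillance: calibrate a cuff to the artery's mean pressure, hold it
there, and read pressure *change* out of pulse-shape change. Because no
public recordings exist for this setting, the package includes a synthetic
PPG/BP/cuff-pressure generator, so every stage runs and is tested without
animal data.

## The method in brief

**Calibration.** During a cuff sweep (150 → 0 mmHg), the PPG pulsation
amplitude — measured as the gap between upper and lower spline envelopes of
the band-passed signal — is maximal where the applied pressure equals the
mean arterial pressure (MAP, the zero-transmural-pressure point). That
pressure becomes the held *constant pressure*.

**Templating.** Under constant pressure, the PPG is filtered to 0.3–20 Hz,
cut into trough-to-trough cycles, and each cycle normalized to amplitude
[0, 1] and 200 samples. With *n* the window size (default 5 cycles),

```
PPG_template = (PPG_norm_1 + ... + PPG_norm_n) / n            (template)
PPG_sample_i = (PPG_norm_i + ... + PPG_norm_{i+n-1}) / n      (i = 3, 4, ...)
```

**Features.** Each sample waveform gives three morphological features:
`f1`, the area between the systolic rising edge and its trough-to-peak
chord; `f2`, the signed area about a baseline at one third of the peak;
`f3`, the summed absolute difference between the sample-vs-template
cross-correlation curve and the template autocorrelation curve
(`f3 = Σ_lag |R_ts − R_tt|`, zero iff the pulse still matches the
template).

**Classification.** Records are labeled *changed* when
`|BP − BP_ref| > threshold` for thresholds 5–15 mmHg, balanced 1:1, and
classified by (a) single-feature threshold rules chosen by Youden's
J = sensitivity + specificity − 1 over 100 candidate cuts, or (b)
tree-based learners (random forest, XGBoost, CART) on `(f1, f2, f3)` —
all under stratified 10-fold cross-validation reporting ACC, ROC-AUC,
MCC, F1, Cohen's kappa and AUPRC. Agreement statistics (Bland–Altman
limits of agreement, British Hypertension Society cumulative-error
grades) are included for estimate-vs-reference comparisons.

## Worked example

```r
library(ppgbp)

# 1. calibrate: where is pulsation maximal on a cuff sweep?
sw <- generate_pressure_sweep(sweep_scenario(true_map = 80, seed = 1))
estimate_constant_pressure(sw$cuff, sw$ppg)
#> [1] 80.59

# 2. a 5-minute simulated bleed: MBP ramps 100 -> 60 mmHg at 5% PPG noise
ses <- generate_bleed_session(
  bleed_scenario(duration = 300, sbp0 = 120, dbp0 = 90,
                 sbp_end = 80, dbp_end = 50, seed = 1),
  pulse_shape()
)
feats <- align_bp(extract_features(preprocess_ppg(ses$ppg), n = 5), ses)
head(tibble::as_tibble(feats)[, c("t_center", "f1", "f2", "f3", "mbp")], 3)
#>   t_center    f1     f2    f3   mbp
#> 1     4.28 12.4  -13.2   182.  99.4
#> 2     4.94  7.87  -7.46  147.  99.3
#> 3     5.89 10.2  -12.5   138.  99.2

# 3. label a 10 mmHg change, balance 1:1, cross-validate a random forest
bal <- balance_dataset(label_delta(feats, "mbp", threshold = 10), seed = 1)
cv <- crossvalidate(bal, "random_forest", k = 10, seed = 1)
glance(cv)
#>   model_id         k acc_mean auc_mean mcc_mean f1_mean kappa_mean auprc_mean ...
#> 1 random_forest   10    0.939    0.986    0.886   0.935      0.879      0.989
```

The estimated constant pressure (80.59 mmHg) sits within a beat's worth of
ramp of the planted 80 mmHg MAP. In the feature table, `f3` grows from ~0
as the pulse departs from its template while MBP falls; the cross-validated
random forest then recognizes >10 mmHg departures from the reference state
with ~94% held-out accuracy on this synthetic session. `autoplot()` methods
exist for traces, CV results and threshold-sweep reports, and
`sweep_delta_bp()` / `sweep_window_size()` drive the full 5–15 mmHg and
2–7-cycle protocol grids.

A thin command-line wrapper with `simulate`, `set-pressure`, `features`,
`sweep-delta` and `agreement` subcommands is installed at
`inst/cli/ppgbp.R`.

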