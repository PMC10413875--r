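---
title: "Detecting blood-pressure variation from PPG pulse morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting blood-pressure variation from PPG pulse morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 3.5)
library(ppgbp)
```

## The problem and the method

Continuous blood-pressure surveillance matters most where it is hardest:
in hypovolemia (progressive blood loss), pressure can drift by tens of
mmHg over minutes, and an arterial catheter is not always an option. The
volume-compensation (vascular-unloading) principle offers a noninvasive
route: when an external cuff pressure equals the mean pressure inside the
artery, the transmural pressure is zero, the vessel wall is maximally
compliant, and the optical pulsation measured by photoplethysmography
(PPG) reaches its largest amplitude.

`ppgbp` implements a pipeline built on that principle:

1. **Constant-pressure calibration.** The cuff sweeps from well above
   systolic pressure down to zero while the PPG is recorded. The upper and
   lower spline envelopes of the band-passed PPG give a peak-to-peak
   pulsation series; the cuff pressure at its maximum is the artery's mean
   pressure, and is then held as the *constant pressure*.
2. **Pulse templating.** Under constant pressure the PPG is band-pass
   filtered (0.3–20 Hz), segmented into trough-to-trough cycles, and each
   cycle is normalized to amplitude $[0,1]$ and exactly 200 samples. The
   *template* is the pointwise mean of the first $n$ normalized cycles
   ($\mathrm{PPG}_{template} = \tfrac{1}{n}\sum_{j=1}^{n}\mathrm{PPG}_{norm,j}$);
   *sample waveforms* are the moving average of $n$ consecutive cycles,
   starting from the third cycle and advancing one cycle per step.
3. **Morphological features.** Each sample waveform yields three numbers:
   * $f_1$ — the area between the systolic rising edge and the straight
     chord from trough to peak (upstroke curvature);
   * $f_2$ — the area above minus the area below a horizontal baseline at
     one third of the peak value (duty-cycle balance);
   * $f_3$ — the summed absolute difference between the sample-vs-template
     cross-correlation curve and the template autocorrelation curve over
     all 399 lags (distance from the reference morphology).
4. **Change classification.** Features are aligned with reference BP,
   labeled as "changed" when $|\mathrm{BP} - \mathrm{BP}_{ref}|$ exceeds a
   threshold (the 11 integers 5–15 mmHg), balanced 1:1, and classified
   either by a single-feature threshold rule selected with Youden's
   $J = \text{sensitivity} + \text{specificity} - 1$ over 100 candidate
   cuts, or by tree-based learners on $(f_1, f_2, f_3)$, all under
   stratified 10-fold cross-validation with six metrics (ACC, ROC-AUC,
   MCC, F1, Cohen's kappa, AUPRC).

The key physiological assumption is that, at constant cuff pressure, pulse
*shape* tracks pressure *level*: as pressure falls the pulse flattens and
broadens, so morphology carries the change signal even though the PPG has
no pressure units of its own.

## The synthetic data generator

No public recordings exist for this setting, so the package ships a
generator that emulates exactly the structure the pipeline relies on, and
every claim the tests make is a claim about this generator.

```{r session}
ses <- generate_bleed_session(
  bleed_scenario(duration = 60, sbp0 = 120, dbp0 = 90,
                 sbp_end = 80, dbp_end = 50, seed = 1),
  pulse_shape()
)
autoplot(ses$ppg) + ggplot2::coord_cartesian(xlim = c(0, 8))
```

A pulse cycle is a two-lobe kernel (systolic plus dicrotic Gaussian lobes,
tapered to zero at both ends so every cycle starts and ends at its
minimum). Two gains tie morphology to mean BP (MBP): `height_gain`
(amplitude loss per mmHg below the reference MBP, default 0.01/mmHg) and
`width_gain` (systolic-peak phase delay per mmHg, default 0.004/mmHg).
With both positive, amplitude is strictly increasing and width strictly
decreasing in MBP — the monotonicity the feature stage exploits. The
defaults are free simulator parameters chosen to give a clearly visible
but not caricatured morphology change over a 40 mmHg bleed; they are not
estimates of any animal's physiology.

A bleed session ramps systolic/diastolic BP linearly from baseline to an
end state (defaults 110/80 → 70/50 mmHg over 300 s, bracketing the
52–119 mmHg span the method targets), derives MBP samplewise as
$\mathrm{DBP} + (\mathrm{SBP} - \mathrm{DBP})/3$ (the standard clinical
estimate), and corrupts the PPG — only — with additive white Gaussian
noise (default sd 0.05, i.e. 5% of the unit pulse amplitude) and a slow
sinusoidal baseline drift (default 0.2 a.u. at 0.05 Hz, below the 0.3 Hz
filter edge so preprocessing can remove it). A pressure sweep ramps the
cuff 150 → 0 mmHg over 60 s and modulates pulsation amplitude as a
Gaussian bell of (cuff − true MAP) with width 20 mmHg.

What the generator does **not** emulate: respiration and autonomic
modulation, motion artifacts, heart-rate variability, reflected-wave
physiology, or any quantitative morphology-vs-pressure law. Passing tests
therefore demonstrate that the pipeline's machinery is correct and
recovers planted structure; they do not certify accuracy on animal or
human recordings.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| band-pass edges | 0.3, 20 | Hz | removes baseline drift and high-frequency noise while keeping ~25 pulse harmonics at 75 bpm |
| filter order | 4 | — | Butterworth prototype; applied forward-backward (zero phase) so trough timing is unshifted |
| heart-rate gate | 30–300 | bpm | discards cycles whose duration is physiologically impossible |
| trough prominence floor | 0.25 | fraction | of the robust (5–95%) signal amplitude; rejects dicrotic-notch minima |
| cycle length | 200 | samples | common grid for templates, samples and correlation curves |
| template window $n$ | 5 | cycles | the protocol's default sliding-window size; swept 2–7 by `sweep_window_size()` |
| window start $i$ | 3 | cycle index | sample waveforms start at the third cycle (1-based) |
| envelope separation | 250 | samples at 500 Hz | ≈ 0.5 s, below one beat at physiological rates; rescaled with the sampling rate |
| change thresholds | 5–15 | mmHg | the 11 integer change levels classified |
| CV folds | 10 | — | stratified, preserving the 1:1 balance per fold |
| ensemble size / depth | 200 / ≤6 | trees / levels | shallow-tree defaults for the three-feature space |

## Numerical choices and degenerate inputs

* **Resampling.** Cycles shorter than 200 samples are interpolated with a
  natural cubic spline. "Downsampling" longer cycles is implemented as
  interpolation onto 200 uniform positions (the same code path): integer
  decimation of non-multiple lengths is ill-defined. A
  `resample_mode = "decimate"` switch preserves the literal
  index-selection reading. Amplitude is min–max rescaled *after*
  resampling so the $[0,1]$ contract holds exactly despite spline
  overshoot.
* **Correlation.** $f_3$ uses full linear (zero-padded) correlation over
  lags $-199\ldots199$; circular correlation is rejected because the
  sliding-product definition is a linear one. The production path uses
  `stats::convolve`; the tests hold it to an independent brute-force
  double loop at $10^{-9}$.
* **Absolute-value reading of $f_3$.** The difference between the two
  correlation curves is summed as $\sum_\ell |R_{t\text{-}s} - R_{t\text{-}t}|$
  — the enclosed area between the curves; a `signed_difference` flag keeps
  the raw signed sum for comparison.
* **Quadrature.** $f_1$/$f_2$ integrate with the trapezoid rule on the
  unit index grid.
* **Tie-breaks.** The constant-pressure estimator breaks exact
  peak-to-peak ties toward the *highest* cuff pressure (over-clamping is
  the conservative error for vascular unloading) and warns when the
  pulsation profile is nearly flat (relative range < 5%). The threshold
  classifier breaks Youden ties toward the smallest cut,
  `greater_is_positive` first.
* **Threshold rule.** The operative selection rule is Youden's $J$; the
  sensitivity/specificity/accuracy-intersection alternative coincides with
  it only in special cases and is not implemented as a separate rule.
* **Degenerate metrics.** Single-class *predictions* define MCC = 0,
  kappa = 0, and F1 = 0 when no true or predicted positives exist;
  single-class *truth* leaves ROC-AUC/AUPRC undefined (error in the
  low-level functions, `NA` + warning in `evaluate_predictions()`).
* **Filter edges.** Zero-phase filtering still has edge transients (the
  0.3 Hz high-pass decays over seconds), so the first/last cycles of a
  segment carry small distortions; the two boundary troughs of a trace are
  additionally invisible to the local-minimum detector. Tests account for
  both rather than pretending ideal edges.

## Design decisions that were genuinely open

* **$\Delta$BP reference state.** The change label needs a reference
  instant. Default: BP averaged over the template window — the template is
  the morphological reference, so the label reference is its hemodynamic
  state. `reference = "previous_sample"` implements the step-to-step
  alternative.
* **Where $f_1$/$f_2$ are computed.** On sample (moving-averaged)
  waveforms, not single cycles, matching the pipeline order in which
  templating precedes feature extraction.
* **Template scope.** The template is fixed per constant-pressure segment
  (the constant pressure defines the reference state); it is not refreshed
  within a segment.
* **Balancing before the CV split**, with stratified folds preserving the
  constructed 1:1 ratio; per-fold threshold fitting is the only
  leakage-free reading of "the optimal threshold was selected".
* **Learner roster.** `random_forest`, `xgboost` and `decision_tree` are
  implemented; `lightgbm`/`catboost` ids raise an explicit dependency
  error rather than silently substituting. Hyperparameter search beyond
  the shallow-tree defaults (e.g. Bayesian optimization) is deliberately
  out of scope: it is tooling around the method, not the method.

## Problem sizes

The test-suite and acceptance runs use 300 s sessions at 500 Hz PPG /
1000 Hz BP (≈ 370 beats, ≈ 360 feature records), five-point MAP-recovery
grids, $2 \times 500$-sample Gaussian classifier checks, and three session
replicates for the classifier summaries — sizes at which every reported
quantity is stable under reseeding while the whole suite runs in minutes.

## A worked pass through the pipeline

```{r pipeline}
sw <- generate_pressure_sweep(sweep_scenario(true_map = 80, seed = 1))
estimate_constant_pressure(sw$cuff, sw$ppg)

cyc <- preprocess_ppg(ses$ppg)
feats <- align_bp(extract_features(cyc, n = 5), ses)
head(tibble::as_tibble(feats), 3)

bal <- balance_dataset(label_delta(feats, "mbp", threshold = 10), seed = 1)
cv <- crossvalidate(bal, "random_forest", k = 10, seed = 1)
glance(cv)
```

## Known limitations

* The simulator's linear BP ramp and constant heart rate are idealized;
  real bleeds have plateaus, reflexes and tachycardia that change pulse
  shape through pathways the generator does not model.
* $f_3$ depends on the template's own window; a corrupted template window
  (artifact in the first $n$ cycles) biases every downstream record.
* The threshold classifier's 100-cut grid spans the *training* range;
  test values outside it are classified by the nearest decision region,
  which is correct but means the cut is not recalibrated to drift.
* Agreement statistics (Bland–Altman, BHS grading) are implemented for
  paired estimate/reference arrays; on synthetic data they describe
  generator recovery, not device accuracy.
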