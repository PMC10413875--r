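#' Pulse shape parameters for the synthetic PPG generator
#'
#' Describes how a single trough-to-trough pulse cycle is drawn and how its
#' morphology responds to mean blood pressure (MBP). The kernel is a
#' two-lobe shape (systolic lobe plus a dicrotic lobe) tapered to zero at
#' both cycle ends, so every generated cycle starts and ends at its minimum.
#' As MBP falls below `map_ref` the systolic peak moves later in the cycle
#' (the pulse widens, rate `width_gain`) and the peak-to-trough amplitude
#' shrinks (rate `height_gain`), emulating the flattening and broadening of
#' the pulse wave seen during progressive blood loss.
#'
#' @param map_ref Reference mean BP (mmHg) at which amplitude is 1 and the
#'   systolic-rise fraction equals `sys_frac`.
#' @param width_gain Shift of the systolic-peak phase per mmHg of MBP drop
#'   (dimensionless per mmHg, >= 0).
#' @param height_gain Amplitude loss per mmHg of MBP drop (per mmHg, >= 0).
#' @param hr Heart rate in beats per minute.
#' @param dicrotic_strength Relative size of the dicrotic lobe, in \[0, 1\].
#' @param sys_frac Systolic-peak phase (fraction of the cycle) at `map_ref`.
#'
#' @return A list of class `pulse_shape`.
#' @export
#' @examples
#' sh <- pulse_shape()
#' cyc <- pulse_cycle(sh, map = 80, n = 400)
#' range(cyc)
pulse_shape <- function(map_ref = 90, width_gain = 0.004, height_gain = 0.01,
                        hr = 75, dicrotic_strength = 0.4, sys_frac = 0.16) {
  if (hr <= 0) stop("`hr` must be positive.", call. = FALSE)
  if (dicrotic_strength < 0 || dicrotic_strength > 1) {
    stop("`dicrotic_strength` must lie in [0, 1].", call. = FALSE)
  }
  if (width_gain < 0 || height_gain < 0) {
    stop("`width_gain` and `height_gain` must be nonnegative.", call. = FALSE)
  }
  structure(
    list(map_ref = map_ref, width_gain = width_gain, height_gain = height_gain,
         hr = hr, dicrotic_strength = dicrotic_strength, sys_frac = sys_frac),
    class = "pulse_shape"
  )
}

#' @rdname pulse_shape
#' @param shape A `pulse_shape`.
#' @param map Mean BP (mmHg) of the beat.
#' @param n Number of samples in the cycle (phase grid `[0, 1)`).
#' @export
pulse_cycle <- function(shape, map, n) {
  stopifnot(inherits(shape, "pulse_shape"), n >= 4, map > 0)
  u <- (seq_len(n) - 1) / n
  # systolic peak phase drifts late as MBP falls; clamped to keep a rise
  p <- min(max(shape$sys_frac + shape$width_gain * (shape$map_ref - map), 0.06), 0.60)
  sys_lobe <- exp(-0.5 * ((u - p) / (0.42 * p))^2)
  dic_lobe <- shape$dicrotic_strength * 0.35 *
    exp(-0.5 * ((u - (p + 0.25)) / 0.10)^2)
  g <- (sys_lobe + dic_lobe) * sin(pi * u)^0.25
  g <- g / max(g)
  amp <- max(0.05, 1 + shape$height_gain * (map - shape$map_ref))
  amp * g
}

#' Generate a PPG pulse train from a per-beat MBP series
#'
#' Concatenates one trough-to-trough cycle per beat. Each cycle's amplitude
#' and systolic-rise fraction are deterministic functions of that beat's MBP
#' (see [pulse_shape()]); with identical MBP values and `noise_sd = 0` all
#' cycles are samplewise identical.
#'
#' @param shape A [pulse_shape()].
#' @param map_series Numeric vector of per-beat mean BP values (mmHg), all
#'   positive.
#' @param fs Sampling rate in Hz.
#' @param noise_sd Standard deviation of additive white Gaussian noise
#'   (amplitude units; 0 for none).
#' @param seed Optional integer seed for the noise.
#'
#' @return A `ppg` [ppg_trace()].
#' @export
#' @examples
#' tr <- generate_pulse_train(pulse_shape(), rep(90, 5), fs = 500)
generate_pulse_train <- function(shape, map_series, fs, noise_sd = 0, seed = NULL) {
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive.", call. = FALSE)
  if (length(map_series) == 0) stop("`map_series` must be nonempty.", call. = FALSE)
  if (any(map_series <= 0)) stop("`map_series` values must be positive.", call. = FALSE)
  n_per_beat <- round(fs * 60 / shape$hr)
  if (n_per_beat < 4) stop("fs too low for one beat at this heart rate.", call. = FALSE)
  samples <- unlist(lapply(map_series, function(m) pulse_cycle(shape, m, n_per_beat)))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    samples <- samples + stats::rnorm(length(samples), sd = noise_sd)
  }
  ppg_trace(samples, fs = fs, channel = "ppg")
}

#' Scenario describing a simulated bleed (hemorrhagic hypovolemia) session
#'
#' Blood pressure falls linearly from a baseline to an end state over the
#' session, emulating continuous blood loss under a constant cuff pressure.
#' Mean BP is derived samplewise as `dbp + (sbp - dbp) / 3`. Additive white
#' Gaussian noise and a slow sinusoidal baseline drift are applied to the
#' PPG channel only; the drift frequency must sit below the 0.3 Hz band-pass
#' edge so preprocessing can remove it.
#'
#' @param duration Session length in seconds.
#' @param fs_ppg PPG sampling rate in Hz (must exceed 40 Hz, i.e. twice the
#'   20 Hz analysis passband).
#' @param fs_bp BP sampling rate in Hz.
#' @param sbp0,dbp0 Baseline systolic/diastolic BP (mmHg).
#' @param sbp_end,dbp_end End-of-bleed systolic/diastolic BP (mmHg).
#' @param noise_sd PPG noise standard deviation (amplitude units; the
#'   noiseless pulse has unit amplitude at the reference MBP).
#' @param drift_amp,drift_freq Amplitude (a.u.) and frequency (Hz, < 0.3) of
#'   the sinusoidal baseline drift.
#' @param seed Integer seed.
#'
#' @return A list of class `bleed_scenario`.
#' @export
bleed_scenario <- function(duration = 300, fs_ppg = 500, fs_bp = 1000,
                           sbp0 = 110, dbp0 = 80, sbp_end = 70, dbp_end = 50,
                           noise_sd = 0.05, drift_amp = 0.2, drift_freq = 0.05,
                           seed = 1L) {
  if (sbp0 <= dbp0 || sbp_end <= dbp_end) {
    stop("systolic BP must exceed diastolic BP at both ends.", call. = FALSE)
  }
  if (fs_ppg <= 40) stop("`fs_ppg` must exceed 40 Hz (2 x 20 Hz passband).", call. = FALSE)
  if (drift_freq >= 0.3) stop("`drift_freq` must be below 0.3 Hz.", call. = FALSE)
  bps <- c(sbp0, dbp0, sbp_end, dbp_end)
  if (any(bps < 40) || any(bps > 130)) {
    stop("BP trajectory must stay within [40, 130] mmHg.", call. = FALSE)
  }
  structure(
    list(duration = duration, fs_ppg = fs_ppg, fs_bp = fs_bp,
         sbp0 = sbp0, dbp0 = dbp0, sbp_end = sbp_end, dbp_end = dbp_end,
         noise_sd = noise_sd, drift_amp = drift_amp, drift_freq = drift_freq,
         seed = as.integer(seed)),
    class = "bleed_scenario"
  )
}

#' Generate a synchronized PPG + invasive-BP bleed session
#'
#' @param scn A [bleed_scenario()].
#' @param shape A [pulse_shape()].
#'
#' @return A list of class `ppg_session` with elements `ppg`, `sbp`, `dbp`,
#'   `mbp` (each a [ppg_trace()] over the same time span), `beats` (a tibble
#'   of per-beat ground truth: start/end time and the SBP/DBP/MBP driving
#'   that beat), and the scenario and shape used.
#' @export
#' @examples
#' ses <- generate_bleed_session(bleed_scenario(duration = 20), pulse_shape())
#' names(ses)
generate_bleed_session <- function(scn, shape = pulse_shape()) {
  stopifnot(inherits(scn, "bleed_scenario"), inherits(shape, "pulse_shape"))
  beat_s <- 60 / shape$hr
  n_beats <- floor(scn$duration / beat_s)
  if (n_beats < 1) stop("`duration` too short for a single beat.", call. = FALSE)
  t_beat <- (seq_len(n_beats) - 1) * beat_s
  frac <- t_beat / scn$duration
  sbp_b <- scn$sbp0 + (scn$sbp_end - scn$sbp0) * frac
  dbp_b <- scn$dbp0 + (scn$dbp_end - scn$dbp0) * frac
  map_b <- dbp_b + (sbp_b - dbp_b) / 3

  ppg <- generate_pulse_train(shape, map_b, fs = scn$fs_ppg)
  set.seed(scn$seed)
  drift <- scn$drift_amp * sin(2 * pi * scn$drift_freq * ppg$time_s)
  noise <- if (scn$noise_sd > 0) stats::rnorm(nrow(ppg), sd = scn$noise_sd) else 0
  ppg <- retrace(ppg, ppg$value + drift + noise)

  span <- nrow(ppg) / scn$fs_ppg
  t_bp <- seq(0, span - 1 / scn$fs_bp, by = 1 / scn$fs_bp)
  sbp_t <- scn$sbp0 + (scn$sbp_end - scn$sbp0) * t_bp / scn$duration
  dbp_t <- scn$dbp0 + (scn$dbp_end - scn$dbp0) * t_bp / scn$duration
  mbp_t <- dbp_t + (sbp_t - dbp_t) / 3

  beats <- tibble::tibble(
    beat = seq_len(n_beats),
    t_start = t_beat,
    t_end = t_beat + beat_s,
    sbp = sbp_b, dbp = dbp_b, mbp = map_b
  )
  structure(
    list(
      ppg = ppg,
      sbp = ppg_trace(sbp_t, fs = scn$fs_bp, channel = "sbp", units = "mmHg"),
      dbp = ppg_trace(dbp_t, fs = scn$fs_bp, channel = "dbp", units = "mmHg"),
      mbp = ppg_trace(mbp_t, fs = scn$fs_bp, channel = "mbp", units = "mmHg"),
      beats = beats, scenario = scn, shape = shape
    ),
    class = "ppg_session"
  )
}

#' Scenario for a cuff-pressure sweep (constant-pressure calibration)
#'
#' Emulates the calibration maneuver: external cuff pressure ramps linearly
#' from `p_start` down to `p_end` while the PPG pulsation amplitude follows a
#' Gaussian bell of (applied pressure - true mean arterial pressure), so the
#' envelope peak-to-peak amplitude is maximal where the applied pressure
#' equals the artery's mean pressure.
#'
#' @param true_map True mean arterial pressure (mmHg); must lie strictly
#'   inside `(p_end, p_start)` or the amplitude maximum is unobservable.
#' @param p_start,p_end Ramp start and end pressures (mmHg).
#' @param ramp_duration Ramp length in seconds.
#' @param pulsation_sd Width (mmHg) of the amplitude-versus-pressure bell.
#' @param fs_ppg Sampling rate (Hz) for both channels.
#' @param noise_sd PPG noise standard deviation (amplitude units).
#' @param seed Integer seed.
#'
#' @return A list of class `sweep_scenario`.
#' @export
sweep_scenario <- function(true_map = 80, p_start = 150, p_end = 0,
                           ramp_duration = 60, pulsation_sd = 20,
                           fs_ppg = 500, noise_sd = 0, seed = 1L) {
  if (!(p_start > p_end) || p_end < 0) {
    stop("need `p_start` > `p_end` >= 0.", call. = FALSE)
  }
  if (!(true_map > p_end && true_map < p_start)) {
    stop("`true_map` must lie strictly inside (p_end, p_start).", call. = FALSE)
  }
  structure(
    list(true_map = true_map, p_start = p_start, p_end = p_end,
         ramp_duration = ramp_duration, pulsation_sd = pulsation_sd,
         fs_ppg = fs_ppg, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "sweep_scenario"
  )
}

#' Generate a cuff-pressure sweep recording
#'
#' @param scn A [sweep_scenario()].
#' @param shape A [pulse_shape()].
#'
#' @return A list of class `ppg_sweep` with elements `cuff` and `ppg`
#'   ([ppg_trace()]s over the same span) and the scenario used.
#' @export
#' @examples
#' sw <- generate_pressure_sweep(sweep_scenario(true_map = 80, ramp_duration = 20))
generate_pressure_sweep <- function(scn, shape = pulse_shape()) {
  stopifnot(inherits(scn, "sweep_scenario"), inherits(shape, "pulse_shape"))
  beat_s <- 60 / shape$hr
  n_beats <- floor(scn$ramp_duration / beat_s)
  if (n_beats < 2) stop("ramp too short: fewer than 2 beats.", call. = FALSE)
  n_per_beat <- round(scn$fs_ppg * beat_s)
  t_center <- ((seq_len(n_beats) - 1) + 0.5) * beat_s
  cuff_at_beat <- scn$p_start +
    (scn$p_end - scn$p_start) * pmin(t_center / scn$ramp_duration, 1)
  amp <- exp(-0.5 * ((cuff_at_beat - scn$true_map) / scn$pulsation_sd)^2)
  base <- pulse_cycle(shape, scn$true_map, n_per_beat)
  samples <- unlist(lapply(amp, function(a) a * base))
  set.seed(scn$seed)
  if (scn$noise_sd > 0) {
    samples <- samples + stats::rnorm(length(samples), sd = scn$noise_sd)
  }
  t <- (seq_along(samples) - 1) / scn$fs_ppg
  cuff <- scn$p_start +
    (scn$p_end - scn$p_start) * pmin(t / scn$ramp_duration, 1)
  structure(
    list(
      cuff = ppg_trace(cuff, fs = scn$fs_ppg, channel = "cuff", units = "mmHg"),
      ppg = ppg_trace(samples, fs = scn$fs_ppg, channel = "ppg"),
      scenario = scn, shape = shape
    ),
    class = "ppg_sweep"
  )
}

#' Width of a pulse cycle at half its maximum
#'
#' Linear interpolation is used at the half-maximum crossings, so the width
#' is a continuous (sub-sample) quantity. Used to verify that simulated
#' pulses broaden as blood pressure falls.
#'
#' @param cycle Numeric vector, one pulse cycle (trough at both ends).
#' @return Width in samples (fractional).
#' @export
width_half_max <- function(cycle) {
  h <- min(cycle) + (max(cycle) - min(cycle)) / 2
  above <- cycle >= h
  idx <- which(above)
  i1 <- idx[1]; i2 <- idx[length(idx)]
  left <- if (i1 > 1) {
    (i1 - 1) + (h - cycle[i1 - 1]) / (cycle[i1] - cycle[i1 - 1])
  } else 1
  right <- if (i2 < length(cycle)) {
    i2 + (h - cycle[i2]) / (cycle[i2 + 1] - cycle[i2])
  } else length(cycle)
  right - left
}
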