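#' Feature 1: rising-edge area of a pulse waveform
#'
#' A straight line is fitted from the cycle trough (index 0, the first
#' sample by the trough-to-trough convention) to the systolic peak, and the
#' area enclosed between the rising-edge curve and that chord is integrated
#' (trapezoid rule on the unit index grid). A steep, concave systolic
#' upstroke encloses a large area; the feature shrinks as the pulse flattens
#' with falling blood pressure.
#'
#' @param w Numeric 200-point waveform (normalized, trough first).
#' @return Rising-edge area (dimensionless index units).
#' @export
#' @examples
#' rising_edge_area(normalize_cycle(sin(pi * seq(0, 1, length.out = 300))))
rising_edge_area <- function(w) {
  check_waveform(w)
  k_peak <- which.max(w)
  if (k_peak == 1) stop("degenerate waveform: peak at the first sample.", call. = FALSE)
  idx <- seq_len(k_peak)
  chord <- w[1] + (w[k_peak] - w[1]) * (idx - 1) / (k_peak - 1)
  pracma::trapz(idx - 1, abs(w[idx] - chord))
}

#' Feature 2: one-third-peak area difference of a pulse waveform
#'
#' One third of the peak value is taken as a horizontal baseline; the
#' feature is the area of the waveform above the baseline minus the area of
#' the gap below it (both areas measured to the baseline, trapezoid rule
#' over all 200 indices). Wider pulses push the balance up; narrow spiky
#' pulses push it down.
#'
#' @inheritParams rising_edge_area
#' @return Signed area difference (dimensionless index units).
#' @export
third_peak_area <- function(w) {
  check_waveform(w)
  base <- max(w) / 3
  idx <- seq_along(w) - 1
  pracma::trapz(idx, pmax(w - base, 0)) - pracma::trapz(idx, pmax(base - w, 0))
}

#' Cross- and auto-correlation curves of a sample waveform and the template
#'
#' Full linear (zero-padded) correlation over lags -199..199:
#' `r_ts[l] = sum_k template[k] * sample[k - l]`, and `r_tt` likewise with
#' the template against itself. `r_tt` is symmetric about lag 0 and maximal
#' there.
#'
#' @param sample,template Numeric 200-point waveforms.
#' @return A tibble with columns `lag` (-199..199), `r_ts`, `r_tt`.
#' @export
correlation_curves <- function(sample, template) {
  check_waveform(sample); check_waveform(template)
  if (length(sample) != length(template)) {
    stop("sample and template must have equal length.", call. = FALSE)
  }
  N <- length(template)
  tibble::tibble(
    lag = -(N - 1):(N - 1),
    r_ts = as.numeric(stats::convolve(template, sample, type = "open")),
    r_tt = as.numeric(stats::convolve(template, template, type = "open"))
  )
}

#' Feature 3: template-correlation difference
#'
#' The sum of absolute differences between the sample-vs-template
#' cross-correlation curve and the template autocorrelation curve, over all
#' 399 lags — the area enclosed between the two curves. It is zero when the
#' sample equals the template and grows as pulse morphology departs from
#' the reference state.
#'
#' @inheritParams correlation_curves
#' @param signed_difference If `TRUE`, sum the raw (signed) differences
#'   instead of their absolute values.
#' @return Nonnegative scalar (zero iff sample == template) when
#'   `signed_difference = FALSE`.
#' @export
template_difference <- function(sample, template, signed_difference = FALSE) {
  cc <- correlation_curves(sample, template)
  d <- cc$r_ts - cc$r_tt
  if (signed_difference) sum(d) else sum(abs(d))
}

check_waveform <- function(w) {
  if (!is.numeric(w) || !all(is.finite(w))) {
    stop("waveform must be finite numeric.", call. = FALSE)
  }
  invisible(w)
}

#' Extract the three morphological features from a normalized cycle set
#'
#' Builds the template from the first `n` normalized cycles, forms the
#' sliding sample waveforms (window `n`, advancing one cycle per step,
#' starting at cycle `start`), and emits one feature record per sample
#' waveform: `f1` (rising-edge area) and `f2` (one-third-peak area
#' difference) computed on the sample waveform, `f3` (correlation
#' difference) computed against the fixed template.
#'
#' @param norm_cycles A normalized `cycle_set` (from [normalize_cycles()] or
#'   [preprocess_ppg()]).
#' @param n Template / sliding-window size in cycles (default 5).
#' @param start First sample-window start cycle (1-based, default 3).
#' @inheritParams template_difference
#'
#' @return A tibble of class `feature_set` with columns `sample_start_cycle`,
#'   `t_start`, `t_end`, `t_center` (window time span, seconds), `f1`, `f2`,
#'   `f3`. The template waveform, window size and the template window's time
#'   span are kept as attributes `template`, `window_cycles`,
#'   `template_span`. Returns an empty tibble with a warning when there are
#'   too few cycles.
#' @export
#' @examples
#' ses <- generate_bleed_session(
#'   bleed_scenario(duration = 40, noise_sd = 0, drift_amp = 0), pulse_shape()
#' )
#' cyc <- preprocess_ppg(ses$ppg)
#' feats <- extract_features(cyc, n = 5)
extract_features <- function(norm_cycles, n = 5, start = 3,
                             signed_difference = FALSE) {
  empty <- tibble::tibble(
    sample_start_cycle = integer(), t_start = numeric(), t_end = numeric(),
    t_center = numeric(), f1 = numeric(), f2 = numeric(), f3 = numeric()
  )
  if (!is.data.frame(norm_cycles) || nrow(norm_cycles) < max(n, start + n - 1)) {
    warning("too few cycles for window size n = ", n, "; returning no features.")
    return(empty)
  }
  template <- make_template(norm_cycles, n)
  sw <- sliding_samples(norm_cycles, n = n, start = start)
  if (nrow(sw) == 0) {
    warning("too few cycles for window size n = ", n, "; returning no features.")
    return(empty)
  }
  t_start <- norm_cycles$t_start[sw$start_cycle]
  t_end <- norm_cycles$t_end[sw$start_cycle + n - 1]
  out <- tibble::tibble(
    sample_start_cycle = sw$start_cycle,
    t_start = t_start,
    t_end = t_end,
    t_center = (t_start + t_end) / 2,
    f1 = vapply(sw$samples, rising_edge_area, numeric(1)),
    f2 = vapply(sw$samples, third_peak_area, numeric(1)),
    f3 = vapply(sw$samples, template_difference, numeric(1),
                template = template, signed_difference = signed_difference)
  )
  attr(out, "template") <- template
  attr(out, "window_cycles") <- n
  attr(out, "template_span") <- c(norm_cycles$t_start[1], norm_cycles$t_end[n])
  class(out) <- c("feature_set", class(out))
  out
}

#' Plot feature series against time, optionally with aligned mean BP
#'
#' @param features A `feature_set` tibble (after [align_bp()] the aligned BP
#'   columns are drawn in a facet of their own).
#' @return A ggplot object.
#' @export
plot_features <- function(features) {
  keep <- intersect(c("f1", "f2", "f3", "sbp", "dbp", "mbp"), names(features))
  long <- tidyr::pivot_longer(
    tibble::as_tibble(features)[c("t_center", keep)],
    -"t_center", names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_center, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
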