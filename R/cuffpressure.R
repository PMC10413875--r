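#' Upper and lower spline envelopes of a pulse trace
#'
#' Finds local maxima (minima) separated by at least `min_separation`
#' samples and interpolates a cubic spline through them at every sample,
#' yielding the upper (lower) envelope of the pulsatile signal. The default
#' separation of 250 samples corresponds to 0.5 s at 500 Hz — safely below
#' one beat interval at physiological heart rates; scale it with the
#' sampling rate.
#'
#' @param trace A [ppg_trace()].
#' @param min_separation Minimum extremum separation in samples.
#'
#' @return A tibble with columns `time_s`, `upper`, `lower` (same length as
#'   the trace; `upper >= lower` pointwise after envelope crossing repair).
#' @export
#' @examples
#' tr <- ppg_trace(sin(2 * pi * 2 * seq(0, 5, by = 1 / 500)), fs = 500)
#' env <- compute_envelope(tr, min_separation = 200)
compute_envelope <- function(trace, min_separation = 250) {
  x <- trace$value
  n <- length(x)
  if (n <= 2 * min_separation) {
    stop("trace too short for the requested `min_separation`.", call. = FALSE)
  }
  peaks <- find_extrema(x, min_separation)
  troughs <- find_extrema(-x, min_separation)
  if (length(peaks) < 2 || length(troughs) < 2) {
    stop("no usable extrema found (is the trace constant?).", call. = FALSE)
  }
  idx <- seq_len(n)
  upper <- stats::spline(peaks, x[peaks], xout = idx, method = "natural")$y
  lower <- stats::spline(troughs, x[troughs], xout = idx, method = "natural")$y
  # spline overshoot can cross the envelopes near the edges; repair pointwise
  swap <- upper < lower
  if (any(swap)) {
    mid <- (upper[swap] + lower[swap]) / 2
    upper[swap] <- mid
    lower[swap] <- mid
  }
  tibble::tibble(time_s = trace$time_s, upper = upper, lower = lower)
}

# local maxima of x, greedily thinned to a minimum separation (taller first)
find_extrema <- function(x, min_sep) {
  n <- length(x)
  if (n < 3) return(integer())
  cand <- which(c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE))
  if (length(cand) == 0) return(integer())
  ord <- cand[order(-x[cand])]
  taken <- rep(FALSE, n)
  keep <- integer()
  for (i in ord) {
    lo <- max(1, i - min_sep); hi <- min(n, i + min_sep)
    if (!any(taken[lo:hi])) {
      keep <- c(keep, i)
      taken[i] <- TRUE
    }
  }
  sort(keep)
}

#' Estimate the constant cuff pressure from a pressure sweep
#'
#' Implements the volume-compensation calibration: as external cuff pressure
#' sweeps past the artery's mean pressure, the PPG pulsation amplitude is
#' maximal where transmural pressure is zero. The PPG is band-pass filtered,
#' its envelope peak-to-peak series computed, lightly smoothed, and the cuff
#' pressure at the peak-to-peak maximum returned as the constant pressure to
#' hold during monitoring.
#'
#' Exact amplitude ties are broken toward the highest cuff pressure
#' (over-clamping is the conservative choice for vascular unloading). A
#' near-flat pulsation profile (relative range < 5%) triggers a warning and
#' the same tie-break.
#'
#' @param sweep_cuff Cuff-pressure [ppg_trace()] (mmHg).
#' @param sweep_ppg Time-aligned PPG [ppg_trace()] over the same span.
#' @param min_separation Envelope extremum separation in samples at 500 Hz;
#'   rescaled internally to the PPG sampling rate.
#' @param smooth_s Moving-average window (seconds) applied to the
#'   peak-to-peak series before the argmax.
#'
#' @return Estimated constant pressure in mmHg (scalar).
#' @export
#' @examples
#' sw <- generate_pressure_sweep(sweep_scenario(true_map = 80))
#' estimate_constant_pressure(sw$cuff, sw$ppg)
estimate_constant_pressure <- function(sweep_cuff, sweep_ppg,
                                       min_separation = 250, smooth_s = 2) {
  fs <- trace_fs(sweep_ppg)
  sep <- max(3L, round(min_separation * fs / 500))
  if (nrow(sweep_ppg) <= 2 * sep) stop("sweep shorter than 2 beats.", call. = FALSE)
  filt <- bandpass(sweep_ppg)
  env <- compute_envelope(filt, min_separation = sep)
  p2p <- env$upper - env$lower
  w <- max(1L, round(smooth_s * fs))
  if (w > 1) {
    p2p <- zoo::rollmean(p2p, w, fill = NA, align = "center")
    p2p <- zoo::na.locf(zoo::na.locf(p2p, na.rm = FALSE), fromLast = TRUE)
  }
  # trim edges where the envelope spline is extrapolating
  trim <- min(sep, floor((length(p2p) - 1) / 2))
  core <- (trim + 1):(length(p2p) - trim)
  p2p_core <- p2p[core]
  cuff_at <- stats::approx(sweep_cuff$time_s, sweep_cuff$value,
                           xout = sweep_ppg$time_s[core], rule = 2)$y
  rng <- range(p2p_core)
  flat <- (rng[2] - rng[1]) < 0.05 * max(rng[2], .Machine$double.eps)
  if (flat) {
    warning("pulsation amplitude is nearly flat across the sweep; ",
            "returning the tie-break (highest) pressure.")
    cand <- seq_along(p2p_core)
  } else {
    cand <- which(p2p_core == rng[2])
  }
  max(cuff_at[cand])
}

#' Bland-Altman agreement analysis
#'
#' @param noninvasive,invasive Equal-length numeric vectors (mmHg).
#' @return A one-row tibble: `bias` (mean difference, noninvasive minus
#'   invasive), `loa_low`, `loa_high` (bias ± 1.96 × SD of the differences,
#'   sample SD with denominator N−1), `outlier_fraction` (fraction of
#'   differences outside the limits), `n`.
#' @export
#' @examples
#' bland_altman(c(100, 90, 80), c(98, 92, 81))
bland_altman <- function(noninvasive, invasive) {
  if (length(noninvasive) != length(invasive)) {
    stop("inputs must have equal length.", call. = FALSE)
  }
  if (length(noninvasive) < 2) stop("need at least 2 paired values.", call. = FALSE)
  d <- noninvasive - invasive
  bias <- mean(d)
  s <- stats::sd(d)
  loa_low <- bias - 1.96 * s
  loa_high <- bias + 1.96 * s
  tibble::tibble(
    bias = bias, loa_low = loa_low, loa_high = loa_high,
    outlier_fraction = mean(d < loa_low | d > loa_high),
    n = length(d)
  )
}

#' British Hypertension Society grading of absolute BP errors
#'
#' Computes the cumulative percentages of absolute errors within 5, 10 and
#' 15 mmHg and assigns the best BHS grade whose three thresholds are all
#' met (A: >= 60/85/95; B: >= 50/75/90; C: >= 40/65/85; otherwise `"none"`).
#'
#' @param abs_errors Nonnegative absolute errors in mmHg.
#' @return A one-row tibble: `cum_pct_5`, `cum_pct_10`, `cum_pct_15`,
#'   `bhs_grade`, `n`.
#' @export
#' @examples
#' bhs_grade(c(2, 3, 4, 8, 12))
bhs_grade <- function(abs_errors) {
  if (length(abs_errors) == 0) stop("empty error vector.", call. = FALSE)
  if (any(abs_errors < 0)) stop("errors must be nonnegative.", call. = FALSE)
  p5 <- 100 * mean(abs_errors <= 5)
  p10 <- 100 * mean(abs_errors <= 10)
  p15 <- 100 * mean(abs_errors <= 15)
  req <- list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))
  grade <- "none"
  for (g in names(req)) {
    if (all(c(p5, p10, p15) >= req[[g]])) { grade <- g; break }
  }
  tibble::tibble(cum_pct_5 = p5, cum_pct_10 = p10, cum_pct_15 = p15,
                 bhs_grade = grade, n = length(abs_errors))
}

#' Pearson product-moment correlation with explicit guards
#'
#' @param x,y Equal-length numeric vectors (length >= 3) with nonzero
#'   variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("inputs must have equal length.", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired values.", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined.", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Full agreement report between a noninvasive estimate and its reference
#'
#' Combines Bland-Altman limits of agreement, Pearson correlation and BHS
#' cumulative-error grading in one row.
#'
#' @inheritParams bland_altman
#' @return A one-row tibble with `bias`, `loa_low`, `loa_high`,
#'   `outlier_fraction`, `pearson_r`, `cum_pct_5/10/15`, `bhs_grade`, `n`.
#' @export
agreement_report <- function(noninvasive, invasive) {
  ba <- bland_altman(noninvasive, invasive)
  bh <- bhs_grade(abs(noninvasive - invasive))
  dplyr::bind_cols(
    ba[c("bias", "loa_low", "loa_high", "outlier_fraction")],
    tibble::tibble(pearson_r = pearson_r(noninvasive, invasive)),
    bh[c("cum_pct_5", "cum_pct_10", "cum_pct_15", "bhs_grade", "n")]
  )
}

#' Bland-Altman plot
#'
#' @inheritParams bland_altman
#' @return A ggplot object: per-pair differences against means, with the
#'   bias and 1.96-SD limits of agreement drawn as horizontal lines.
#' @export
plot_bland_altman <- function(noninvasive, invasive) {
  ba <- bland_altman(noninvasive, invasive)
  df <- tibble::tibble(
    mean_bp = (noninvasive + invasive) / 2,
    diff_bp = noninvasive - invasive
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_bp, y = .data$diff_bp)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high), linetype = "dashed") +
    ggplot2::labs(x = "mean of methods (mmHg)", y = "difference (mmHg)",
                  title = sprintf("Bland-Altman: bias %.2f, LoA [%.2f, %.2f] mmHg",
                                  ba$bias, ba$loa_low, ba$loa_high)) +
    ggplot2::theme_minimal()
}
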