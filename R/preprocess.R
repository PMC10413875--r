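#' Zero-phase Butterworth band-pass filter
#'
#' Retains the 0.3–20 Hz band of the pulse signal, removing baseline drift
#' and low/high-frequency noise. Filtering is applied forward and backward
#' (zero phase) so trough timing is not shifted by the filter's group delay.
#'
#' @param trace A [ppg_trace()].
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs / 2`.
#' @param order Butterworth prototype order (the band-pass has twice this
#'   many poles).
#' @param invert If `TRUE` the signal is negated first (raw transmission-mode
#'   devices record the optical signal upside-down relative to the pressure
#'   pulse; the simulator emits upright pulses, so the default is `FALSE`).
#'
#' @return A filtered [ppg_trace()] of the same length.
#' @export
#' @examples
#' tr <- generate_pulse_train(pulse_shape(), rep(90, 10), fs = 500)
#' filt <- bandpass(tr)
bandpass <- function(trace, low = 0.3, high = 20, order = 4, invert = FALSE) {
  fs <- trace_fs(trace)
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("need 0 < low < high < fs/2 (got low = ", low, ", high = ", high,
         ", fs = ", fs, ").", call. = FALSE)
  }
  x <- trace$value
  if (invert) x <- -x
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  retrace(trace, as.numeric(y))
}

#' Reject invalid (flat or clipped) signal segments
#'
#' Scans the trace with a rolling window and drops windows that are flat
#' (rolling standard deviation below `flat_sd_thresh`, e.g. a disconnected
#' sensor) or clipped (more than `clip_fraction_thresh` of the window's
#' samples pinned at the trace extremes). The remaining samples are returned
#' as maximal contiguous valid segments.
#'
#' @param trace A [ppg_trace()].
#' @param flat_sd_thresh Rolling-sd floor (amplitude units).
#' @param clip_fraction_thresh Maximum tolerated fraction of clipped samples
#'   per window.
#' @param window_s Rolling window length in seconds.
#'
#' @return A list of [ppg_trace()] segments (possibly empty).
#' @export
reject_invalid <- function(trace, flat_sd_thresh = 1e-4,
                           clip_fraction_thresh = 0.1, window_s = 1) {
  stopifnot(flat_sd_thresh >= 0, clip_fraction_thresh >= 0)
  fs <- trace_fs(trace)
  x <- trace$value
  w <- max(3, round(window_s * fs))
  if (length(x) < w) {
    return(if (stats::sd(x) < flat_sd_thresh) list() else list(trace))
  }
  roll_sd <- zoo::rollapply(x, w, stats::sd, fill = NA, align = "center")
  # extend the centered rolling stat to the edges
  roll_sd <- zoo::na.locf(zoo::na.locf(roll_sd, na.rm = FALSE), fromLast = TRUE)
  rng <- range(x)
  tol <- max(1e-12, diff(rng) * 1e-6)
  clipped <- (x <= rng[1] + tol) | (x >= rng[2] - tol)
  roll_clip <- zoo::rollapply(as.numeric(clipped), w, mean, fill = NA, align = "center")
  roll_clip <- zoo::na.locf(zoo::na.locf(roll_clip, na.rm = FALSE), fromLast = TRUE)
  valid <- roll_sd >= flat_sd_thresh & roll_clip <= clip_fraction_thresh
  if (!any(valid)) return(list())
  runs <- rle(valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    ppg_trace(x[idx], fs = fs, t0 = trace$time_s[idx[1]],
              channel = trace_channel(trace), units = attr(trace, "units") %||% "a.u.")
  })
}

#' Segment a pulse trace into trough-to-trough cycles
#'
#' A pulse cycle runs from one waveform trough to the next. Troughs are
#' local minima separated by at least one minimum beat interval, retained
#' only if sufficiently prominent (the dip below the surrounding signal must
#' exceed `prominence_frac` of the trace's robust beat amplitude). Cycles
#' whose duration falls outside the physiological heart-rate band are
#' discarded.
#'
#' @param trace A band-passed, upright-polarity [ppg_trace()].
#' @param min_hr,max_hr Admissible heart-rate band in beats per minute.
#' @param prominence_frac Trough prominence floor, as a fraction of the
#'   robust (5–95 percentile) signal amplitude.
#'
#' @return A tibble of class `cycle_set` with one row per retained cycle:
#'   `cycle` (index), `start_idx`, `end_idx` (0-based sample indices of the
#'   bounding troughs), `t_start`, `t_end` (seconds), `duration_s`, and
#'   `samples` (list-column of raw sample vectors). The sampling rate is
#'   kept in attribute `fs`.
#' @export
segment_cycles <- function(trace, min_hr = 30, max_hr = 300,
                           prominence_frac = 0.25) {
  fs <- trace_fs(trace)
  x <- trace$value
  min_sep <- floor(fs * 60 / max_hr)
  n <- length(x)
  empty <- tibble::tibble(
    cycle = integer(), start_idx = integer(), end_idx = integer(),
    t_start = numeric(), t_end = numeric(), duration_s = numeric(),
    samples = list()
  )
  attr(empty, "fs") <- fs
  class(empty) <- c("cycle_set", class(empty))

  is_min <- c(FALSE, x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n], FALSE)
  cand <- which(is_min)
  if (length(cand) < 2) {
    warning("fewer than 2 troughs found; returning an empty cycle set.")
    return(empty)
  }
  # prominence gate first: secondary minima (e.g. the dicrotic notch) have
  # tiny prominence and must not survive into the separation thinning
  amp <- diff(stats::quantile(x, c(0.05, 0.95), names = FALSE))
  floor_p <- prominence_frac * amp
  if (floor_p > 0) {
    prom <- vapply(cand, function(i) trough_prominence(x, i), numeric(1))
    cand <- cand[prom >= floor_p]
  }
  if (length(cand) < 2) {
    warning("fewer than 2 prominent troughs; returning an empty cycle set.")
    return(empty)
  }
  # enforce minimum separation, keeping the deeper trough on conflict
  ord <- cand[order(x[cand])]
  keep <- logical(n)
  taken <- rep(FALSE, n)
  for (i in ord) {
    lo <- max(1, i - min_sep); hi <- min(n, i + min_sep)
    if (!any(taken[lo:hi])) {
      keep[i] <- TRUE
      taken[i] <- TRUE
    }
  }
  troughs <- sort(which(keep))
  if (length(troughs) < 2) {
    warning("fewer than 2 prominent troughs; returning an empty cycle set.")
    return(empty)
  }
  dur <- diff(troughs) / fs
  ok <- dur >= 60 / max_hr & dur <= 60 / min_hr
  starts <- troughs[-length(troughs)][ok]
  ends <- troughs[-1][ok]
  if (length(starts) == 0) {
    warning("no cycles within the heart-rate band; returning an empty cycle set.")
    return(empty)
  }
  out <- tibble::tibble(
    cycle = seq_along(starts),
    start_idx = starts - 1L,
    end_idx = ends - 1L,
    t_start = trace$time_s[starts],
    t_end = trace$time_s[ends],
    duration_s = (ends - starts) / fs,
    samples = purrr::map2(starts, ends, function(s, e) x[s:(e - 1)])
  )
  attr(out, "fs") <- fs
  class(out) <- c("cycle_set", class(out))
  out
}

#' Normalize one pulse cycle to unit amplitude and 200 samples
#'
#' Amplitude is min–max rescaled to \[0, 1\] and the cycle is resampled to
#' exactly 200 points. Cycles shorter than 200 samples are interpolated with
#' a cubic spline; longer cycles are, by default, interpolated onto 200
#' uniformly spaced positions (`resample_mode = "interp"`), or decimated by
#' index selection (`"decimate"`).
#'
#' @param cycle Numeric vector of raw samples (length >= 4, non-flat).
#' @param resample_mode `"interp"` (default) or `"decimate"` for cycles
#'   longer than 200 samples.
#'
#' @return Numeric vector of length 200 with `min == 0` and `max == 1`.
#' @export
#' @examples
#' w <- normalize_cycle(sin(pi * seq(0, 1, length.out = 400)))
#' length(w); range(w)
normalize_cycle <- function(cycle, resample_mode = c("interp", "decimate")) {
  resample_mode <- match.arg(resample_mode)
  L <- length(cycle)
  if (L < 4) stop("cycle too short (need >= 4 samples).", call. = FALSE)
  if (max(cycle) == min(cycle)) stop("degenerate (flat) cycle.", call. = FALSE)
  if (L == 200) {
    y <- cycle
  } else if (L > 200 && resample_mode == "decimate") {
    y <- cycle[round(seq(1, L, length.out = 200))]
  } else {
    xo <- seq(0, 1, length.out = 200)
    y <- stats::spline(x = seq(0, 1, length.out = L), y = cycle, xout = xo,
                       method = "natural")$y
  }
  (y - min(y)) / (max(y) - min(y))
}

#' @rdname normalize_cycle
#' @param cycles A `cycle_set` from [segment_cycles()].
#' @return `normalize_cycles()` returns the cycle-set tibble with an added
#'   list-column `norm` of 200-point normalized waveforms.
#' @export
normalize_cycles <- function(cycles, resample_mode = c("interp", "decimate")) {
  resample_mode <- match.arg(resample_mode)
  dplyr::mutate(
    cycles,
    norm = purrr::map(.data$samples, normalize_cycle, resample_mode = resample_mode)
  )
}

#' Pulse-wave template: mean of the first n normalized cycles
#'
#' The template waveform is the pointwise arithmetic mean of the first `n`
#' normalized cycles of a constant-pressure segment; it serves as the
#' morphological reference that sample waveforms are compared against.
#'
#' @param norm_cycles A list of 200-point normalized cycles, or a tibble
#'   with a `norm` list-column (as from [normalize_cycles()]).
#' @param n Number of leading cycles to average (default 5).
#'
#' @return Numeric vector of length 200.
#' @export
make_template <- function(norm_cycles, n = 5) {
  w <- as_waveform_list(norm_cycles)
  if (n < 1) stop("`n` must be >= 1.", call. = FALSE)
  if (length(w) < n) {
    stop("need at least n = ", n, " cycles (got ", length(w), ").", call. = FALSE)
  }
  Reduce(`+`, w[seq_len(n)]) / n
}

#' Sliding sample waveforms: moving average of n normalized cycles
#'
#' Starting from cycle `start` (1-based; the convention skips the first two
#' cycles), each window of `n` consecutive normalized cycles is averaged
#' pointwise into one sample waveform; the window advances one cycle per
#' step until the last cycle of the segment is included.
#'
#' @inheritParams make_template
#' @param start First window start index (1-based; default 3).
#'
#' @return A tibble with columns `start_cycle` and a list-column `samples`
#'   of 200-point waveforms (empty if too few cycles).
#' @export
sliding_samples <- function(norm_cycles, n = 5, start = 3) {
  w <- as_waveform_list(norm_cycles)
  N <- length(w)
  if (N < n || start + n - 1 > N) {
    return(tibble::tibble(start_cycle = integer(), samples = list()))
  }
  starts <- seq.int(start, N - n + 1)
  tibble::tibble(
    start_cycle = starts,
    samples = lapply(starts, function(i) Reduce(`+`, w[i:(i + n - 1)]) / n)
  )
}

# classic (topographic) prominence of a local minimum: its depth below the
# lower of the two maxima separating it from the nearest deeper samples
trough_prominence <- function(x, i) {
  n <- length(x)
  lower_left <- which(x[seq_len(i - 1)] < x[i])
  j <- if (length(lower_left)) max(lower_left) else 1L
  left_max <- max(x[j:i])
  right <- if (i < n) which(x[(i + 1):n] < x[i]) else integer()
  k <- if (length(right)) i + min(right) else n
  right_max <- max(x[i:k])
  min(left_max, right_max) - x[i]
}

as_waveform_list <- function(x) {
  if (is.data.frame(x)) {
    if (!"norm" %in% names(x)) {
      stop("expected a `norm` list-column (run normalize_cycles() first).",
           call. = FALSE)
    }
    x <- x$norm
  }
  stopifnot(is.list(x))
  bad <- !vapply(x, function(w) is.numeric(w) && length(w) == 200, logical(1))
  if (any(bad)) stop("all waveforms must be numeric and 200 points long.", call. = FALSE)
  x
}

#' Run the full preprocessing chain on a PPG trace
#'
#' Convenience wrapper: band-pass filter, invalid-segment rejection, cycle
#' segmentation and normalization on the longest valid segment.
#'
#' @inheritParams bandpass
#' @inheritParams segment_cycles
#' @inheritParams normalize_cycle
#' @return A normalized `cycle_set` tibble (see [normalize_cycles()]).
#' @export
preprocess_ppg <- function(trace, low = 0.3, high = 20, order = 4,
                           invert = FALSE, min_hr = 30, max_hr = 300,
                           resample_mode = c("interp", "decimate")) {
  resample_mode <- match.arg(resample_mode)
  filt <- bandpass(trace, low = low, high = high, order = order, invert = invert)
  segs <- reject_invalid(filt)
  if (length(segs) == 0) stop("no valid signal segments found.", call. = FALSE)
  seg <- segs[[which.max(vapply(segs, nrow, integer(1)))]]
  cyc <- segment_cycles(seg, min_hr = min_hr, max_hr = max_hr)
  normalize_cycles(cyc, resample_mode = resample_mode)
}

#' Write / read waveform matrices (cycles, templates, samples) as CSV
#'
#' Rows are waveforms, 200 columns of amplitudes; a JSON sidecar records the
#' window size and provenance.
#'
#' @param waveforms List of 200-point waveforms or a tibble with a `norm` or
#'   `samples` list-column.
#' @param path CSV path.
#' @param meta Named list for the sidecar.
#' @export
write_waveforms <- function(waveforms, path, meta = list()) {
  if (is.data.frame(waveforms)) {
    col <- intersect(c("norm", "samples"), names(waveforms))[1]
    if (is.na(col)) stop("no waveform list-column found.", call. = FALSE)
    waveforms <- waveforms[[col]]
  }
  m <- do.call(rbind, waveforms)
  colnames(m) <- paste0("p", seq_len(ncol(m)))
  readr::write_csv(tibble::as_tibble(m), path)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_waveforms
#' @export
read_waveforms <- function(path) {
  m <- as.matrix(readr::read_csv(path, show_col_types = FALSE))
  lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
}
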