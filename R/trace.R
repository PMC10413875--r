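#' Construct a uniformly sampled signal trace
#'
#' A `ppg_trace` is a tibble with columns `time_s` and `value`, carrying the
#' sampling rate and channel identity as attributes. All signal-level
#' functions in the package (filtering, segmentation, envelope extraction,
#' the simulator) consume and return this container.
#'
#' @param value Numeric vector of samples.
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds.
#' @param channel One of `"ppg"`, `"cuff"`, `"sbp"`, `"dbp"`, `"mbp"`.
#' @param units Unit label for `value` (informational).
#'
#' @return A tibble of class `ppg_trace` with columns `time_s`, `value`.
#' @export
#' @examples
#' tr <- ppg_trace(sin(2 * pi * 1.25 * seq(0, 4, by = 1 / 500)), fs = 500)
#' trace_fs(tr)
ppg_trace <- function(value, fs, t0 = 0, channel = "ppg", units = "a.u.") {
  stopifnot(is.numeric(value), length(value) >= 1)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a single positive number (Hz).", call. = FALSE)
  }
  if (!all(is.finite(value))) {
    stop("trace samples must all be finite.", call. = FALSE)
  }
  channel <- match.arg(channel, c("ppg", "cuff", "sbp", "dbp", "mbp"))
  out <- tibble::tibble(
    time_s = t0 + (seq_along(value) - 1) / fs,
    value = as.numeric(value)
  )
  attr(out, "fs") <- fs
  attr(out, "channel") <- channel
  attr(out, "units") <- units
  class(out) <- c("ppg_trace", class(out))
  out
}

#' @rdname ppg_trace
#' @param x A `ppg_trace`.
#' @export
trace_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) stop("not a ppg_trace: missing `fs` attribute.", call. = FALSE)
  fs
}

#' @rdname ppg_trace
#' @export
trace_channel <- function(x) attr(x, "channel") %||% "ppg"

# rebuild a trace from an existing one with new samples (same fs/channel)
retrace <- function(x, value, t0 = x$time_s[1]) {
  ppg_trace(value, fs = trace_fs(x), t0 = t0,
            channel = trace_channel(x), units = attr(x, "units") %||% "a.u.")
}

#' Write / read a signal trace as delimited text with a JSON sidecar
#'
#' The on-disk format is a two-column CSV (`time_s,value`) plus a
#' `<path>.json` sidecar recording the sampling rate, channel, units and any
#' extra metadata (e.g. simulator scenario parameters and seed).
#'
#' @param x A `ppg_trace`.
#' @param path CSV file path.
#' @param meta Named list of extra metadata for the sidecar.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns a
#'   `ppg_trace`.
#' @export
write_trace <- function(x, path, meta = list()) {
  readr::write_csv(tibble::as_tibble(x)[c("time_s", "value")], path)
  sidecar <- c(
    list(fs = trace_fs(x), channel = trace_channel(x),
         units = attr(x, "units") %||% "a.u."),
    meta
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "value") %in% names(tab))) {
    stop("trace CSV must have columns `time_s` and `value`.", call. = FALSE)
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    fs <- meta$fs
    channel <- meta$channel %||% "ppg"
    units <- meta$units %||% "a.u."
  } else {
    dt <- diff(tab$time_s)
    fs <- 1 / stats::median(dt)
    channel <- "ppg"
    units <- "a.u."
  }
  ppg_trace(tab$value, fs = fs, t0 = tab$time_s[1], channel = channel, units = units)
}

#' @importFrom rlang %||%
NULL

#' @export
autoplot.ppg_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)",
      y = attr(object, "units") %||% "value",
      title = paste0(trace_channel(object), " trace (fs = ", trace_fs(object), " Hz)")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
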