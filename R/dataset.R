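#' Align invasive BP with extracted feature records
#'
#' Each feature record receives the mean of each BP channel over its
#' window's time span. The reference hemodynamic state — the mean BP over
#' the template window (the same cycles that define the pulse template) —
#' is stored in attribute `template_bp` for use by [label_delta()].
#'
#' @param features A `feature_set` from [extract_features()].
#' @param session Either a `ppg_session` (from [generate_bleed_session()])
#'   or a named list with `sbp`, `dbp`, `mbp` [ppg_trace()]s covering the
#'   feature time span.
#'
#' @return The feature tibble with added `sbp`, `dbp`, `mbp` columns.
#' @export
align_bp <- function(features, session) {
  traces <- session[c("sbp", "dbp", "mbp")]
  if (any(vapply(traces, is.null, logical(1)))) {
    stop("`session` must provide sbp, dbp and mbp traces.", call. = FALSE)
  }
  span <- range(traces$mbp$time_s)
  if (any(features$t_start < span[1] - 1e-9) || any(features$t_end > span[2] + 1e-9)) {
    stop("feature windows fall outside the BP trace span.", call. = FALSE)
  }
  window_mean <- function(tr, a, b) {
    mean(tr$value[tr$time_s >= a & tr$time_s <= b])
  }
  out <- dplyr::mutate(
    features,
    sbp = purrr::map2_dbl(.data$t_start, .data$t_end, ~window_mean(traces$sbp, .x, .y)),
    dbp = purrr::map2_dbl(.data$t_start, .data$t_end, ~window_mean(traces$dbp, .x, .y)),
    mbp = purrr::map2_dbl(.data$t_start, .data$t_end, ~window_mean(traces$mbp, .x, .y))
  )
  tspan <- attr(features, "template_span")
  if (!is.null(tspan)) {
    a <- max(tspan[1], span[1]); b <- min(tspan[2], span[2])
    attr(out, "template_bp") <- c(
      sbp = window_mean(traces$sbp, a, b),
      dbp = window_mean(traces$dbp, a, b),
      mbp = window_mean(traces$mbp, a, b)
    )
  }
  for (a in c("template", "window_cycles", "template_span")) {
    attr(out, a) <- attr(features, a)
  }
  class(out) <- unique(c("feature_set", class(out)))
  out
}

#' Label BP change relative to a reference state
#'
#' For each feature record, `delta_bp = |BP - BP_ref|` for the chosen BP
#' channel; records whose change exceeds the threshold are labeled 1
#' ("BP changed"), others 0 ("no change"). The default reference is the BP
#' over the template window of the constant-pressure segment (the
#' morphological reference's own hemodynamic state); the alternative
#' `"previous_sample"` references each record to its predecessor.
#'
#' @param features_bp A `feature_set` with aligned BP columns
#'   (see [align_bp()]).
#' @param bp_kind One of `"sbp"`, `"dbp"`, `"mbp"`.
#' @param threshold Change threshold in mmHg (the protocol uses the 11
#'   integers 5..15).
#' @param reference `"segment_start"` (default: template-window BP) or
#'   `"previous_sample"`.
#' @param ref_value Optional explicit reference BP (mmHg), overriding
#'   `reference`.
#'
#' @return A tibble with columns `f1`, `f2`, `f3`, `delta_bp`, `label`
#'   (integer 0/1), `bp_kind`, `threshold`.
#' @export
label_delta <- function(features_bp, bp_kind = c("mbp", "sbp", "dbp"),
                        threshold = 5,
                        reference = c("segment_start", "previous_sample"),
                        ref_value = NULL) {
  bp_kind <- match.arg(bp_kind)
  reference <- match.arg(reference)
  if (!bp_kind %in% names(features_bp)) {
    stop("column `", bp_kind, "` not found; run align_bp() first.", call. = FALSE)
  }
  bp <- features_bp[[bp_kind]]
  if (!is.null(ref_value)) {
    delta <- abs(bp - ref_value)
  } else if (reference == "segment_start") {
    tbp <- attr(features_bp, "template_bp")
    ref <- if (!is.null(tbp)) unname(tbp[bp_kind]) else bp[1]
    delta <- abs(bp - ref)
  } else {
    delta <- abs(bp - dplyr::lag(bp, default = bp[1]))
  }
  tibble::tibble(
    f1 = features_bp$f1, f2 = features_bp$f2, f3 = features_bp$f3,
    delta_bp = delta,
    label = as.integer(delta > threshold),
    bp_kind = bp_kind,
    threshold = threshold
  )
}

#' Balance a labeled dataset to a 1:1 class ratio
#'
#' The majority class is randomly undersampled (seeded) to the minority
#' count and the rows shuffled; every minority-class sample is kept. A 1:1
#' ratio prevents the classifiers from drifting toward the prevalent class.
#'
#' @param samples A labeled tibble with a 0/1 `label` column.
#' @param seed Integer seed for the undersampling.
#'
#' @return A tibble of class `balanced_set` with equal class counts;
#'   attributes `n_pos`, `n_neg`, `seed`.
#' @export
balance_dataset <- function(samples, seed = 1L) {
  n_pos <- sum(samples$label == 1)
  n_neg <- sum(samples$label == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("cannot balance: the ", if (n_pos == 0) "positive" else "negative",
         " class is empty.", call. = FALSE)
  }
  set.seed(seed)
  m <- min(n_pos, n_neg)
  idx_pos <- sample(which(samples$label == 1), m)
  idx_neg <- sample(which(samples$label == 0), m)
  out <- samples[sample(c(idx_pos, idx_neg)), ]
  attr(out, "n_pos") <- m
  attr(out, "n_neg") <- m
  attr(out, "seed") <- as.integer(seed)
  class(out) <- unique(c("balanced_set", class(out)))
  out
}

#' Build labeled (optionally balanced) datasets for a session
#'
#' Convenience driver: preprocess the session's PPG, extract features,
#' align BP and label at each requested threshold.
#'
#' @param session A `ppg_session`.
#' @param n Template / window size in cycles.
#' @inheritParams label_delta
#' @param thresholds Integer vector of change thresholds in mmHg.
#' @param balance If `TRUE`, balance each threshold's dataset 1:1.
#' @param seed Seed for balancing.
#' @return A named list of labeled tibbles, one per threshold.
#' @export
build_datasets <- function(session, n = 5, bp_kind = "mbp", thresholds = 5:15,
                           reference = "segment_start", balance = TRUE,
                           seed = 1L) {
  cyc <- preprocess_ppg(session$ppg)
  feats <- align_bp(extract_features(cyc, n = n), session)
  out <- lapply(thresholds, function(th) {
    lab <- label_delta(feats, bp_kind = bp_kind, threshold = th,
                       reference = reference)
    if (!balance) return(lab)
    if (sum(lab$label == 1) == 0 || sum(lab$label == 0) == 0) return(NULL)
    balance_dataset(lab, seed = seed)
  })
  names(out) <- paste0("thr", thresholds)
  out
}

#' Write a labeled dataset as CSV
#'
#' Columns `f1,f2,f3,delta_bp,label,bp_kind,threshold`.
#'
#' @param samples Labeled tibble.
#' @param path CSV path.
#' @export
write_dataset <- function(samples, path) {
  readr::write_csv(
    samples[c("f1", "f2", "f3", "delta_bp", "label", "bp_kind", "threshold")],
    path
  )
  invisible(path)
}
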