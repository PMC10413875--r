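#' Fit a single-feature threshold classifier by Youden's index
#'
#' The training feature's range is spanned by 100 equally spaced candidate
#' cuts (inclusive of both endpoints). For every cut and both decision
#' directions (`greater_is_positive`: predict change when the feature
#' exceeds the cut; `less_is_positive`: the reverse) sensitivity and
#' specificity are computed on the training set, and the (cut, direction)
#' maximizing Youden's J = sensitivity + specificity − 1 is selected. Ties
#' go to the smallest cut, `greater_is_positive` first.
#'
#' @param train Labeled tibble with the feature column and a 0/1 `label`.
#' @param feature_id One of `"f1"`, `"f2"`, `"f3"` (or any numeric column
#'   name present in `train`).
#' @param n_cuts Number of candidate cuts (default 100).
#'
#' @return An object of class `ppg_threshold_model` with elements
#'   `feature_id`, `cut`, `direction`, `youden_j`, `range`.
#' @export
#' @examples
#' d <- tibble::tibble(f2 = c(1, 2, 3, 4), label = c(0L, 0L, 1L, 1L))
#' m <- fit_threshold(d, "f2")
#' predict(m, d)
fit_threshold <- function(train, feature_id = "f2", n_cuts = 100) {
  x <- train[[feature_id]]
  if (is.null(x)) stop("feature column `", feature_id, "` not found.", call. = FALSE)
  y <- train$label
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant training feature: no threshold exists.", call. = FALSE)
  cuts <- seq(rng[1], rng[2], length.out = n_cuts)
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0 || nn == 0) stop("training labels must contain both classes.", call. = FALSE)
  eval_dir <- function(direction) {
    vapply(cuts, function(cut) {
      pred <- if (direction == "greater_is_positive") x > cut else x < cut
      sens <- sum(pred & y == 1) / np
      spec <- sum(!pred & y == 0) / nn
      sens + spec - 1
    }, numeric(1))
  }
  grid <- tibble::tibble(
    cut = rep(cuts, 2),
    direction = rep(c("greater_is_positive", "less_is_positive"), each = n_cuts),
    j = c(eval_dir("greater_is_positive"), eval_dir("less_is_positive"))
  )
  grid <- grid[order(-grid$j, grid$cut,
                     match(grid$direction,
                           c("greater_is_positive", "less_is_positive"))), ]
  best <- grid[1, ]
  structure(
    list(feature_id = feature_id, cut = best$cut, direction = best$direction,
         youden_j = best$j, range = rng),
    class = "ppg_threshold_model"
  )
}

#' @export
predict.ppg_threshold_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- newdata[[object$feature_id]]
  score <- if (object$direction == "greater_is_positive") x - object$cut else object$cut - x
  if (type == "score") return(score)
  as.integer(score > 0)
}

#' @export
print.ppg_threshold_model <- function(x, ...) {
  cat("Single-feature threshold classifier (Youden's J selection)\n")
  cat(sprintf("  feature: %s   cut: %.6g   direction: %s   training J: %.3f\n",
              x$feature_id, x$cut, x$direction, x$youden_j))
  invisible(x)
}

#' @export
tidy.ppg_threshold_model <- function(x, ...) {
  tibble::tibble(feature_id = x$feature_id, cut = x$cut,
                 direction = x$direction, youden_j = x$youden_j)
}

#' Fit a multi-feature tree-based classifier on (f1, f2, f3)
#'
#' Available learners are `random_forest` (randomForest), `xgboost`
#' (gradient-boosted trees) and `decision_tree` (CART via rpart), with
#' shallow trees (depth <= 6) and 200 estimators for the ensembles as
#' defaults. The learner ids `lightgbm` and `catboost` are recognized but
#' require their respective packages; without them a clear dependency error
#' is raised (never a silent fallback).
#'
#' @param train Balanced labeled tibble with columns `f1`, `f2`, `f3`,
#'   `label`.
#' @param model_id One of `"random_forest"`, `"xgboost"`, `"decision_tree"`,
#'   `"lightgbm"`, `"catboost"`.
#' @param seed Integer seed (the tree learners are stochastic).
#' @param params Named list of overrides for the learner's defaults.
#'
#' @return An object of class `ppg_ml_model`.
#' @export
fit_multifeature <- function(train, model_id, seed = 1L, params = list()) {
  valid <- c("random_forest", "xgboost", "decision_tree", "lightgbm", "catboost")
  if (!model_id %in% valid) {
    stop("unknown model_id `", model_id, "`; valid ids: ",
         paste(valid, collapse = ", "), ".", call. = FALSE)
  }
  if (model_id %in% c("lightgbm", "catboost")) {
    stop("the `", model_id, "` learner requires the ", model_id,
         " R package, which is not installed; install it or choose one of ",
         "random_forest, xgboost, decision_tree.", call. = FALSE)
  }
  feats <- c("f1", "f2", "f3")
  if (!all(feats %in% names(train))) {
    stop("training data must have columns f1, f2, f3.", call. = FALSE)
  }
  X <- as.data.frame(train[feats])
  y <- factor(train$label, levels = c(0, 1))
  set.seed(seed)
  fit <- switch(
    model_id,
    random_forest = do.call(randomForest::randomForest, c(
      list(x = X, y = y),
      utils::modifyList(list(ntree = 200), params)
    )),
    xgboost = {
      p <- utils::modifyList(
        list(nrounds = 200, max_depth = 6, eta = 0.1,
             objective = "binary:logistic", nthread = 1),
        params
      )
      nrounds <- p$nrounds
      p$nrounds <- NULL
      dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = train$label)
      xgboost::xgb.train(params = p, data = dtrain, nrounds = nrounds,
                         verbose = 0)
    },
    decision_tree = do.call(rpart::rpart, c(
      list(formula = label ~ f1 + f2 + f3,
           data = cbind(X, label = y), method = "class"),
      list(control = do.call(rpart::rpart.control,
                             utils::modifyList(list(maxdepth = 6), params)))
    ))
  )
  structure(list(model_id = model_id, fit = fit, features = feats, seed = seed),
            class = "ppg_ml_model")
}

#' @export
predict.ppg_ml_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.data.frame(newdata[object$features])
  score <- switch(
    object$model_id,
    random_forest = unname(predict(object$fit, X, type = "prob")[, "1"]),
    xgboost = as.numeric(predict(object$fit, xgboost::xgb.DMatrix(as.matrix(X)))),
    decision_tree = unname(predict(object$fit, X, type = "prob")[, "1"])
  )
  if (type == "score") return(score)
  as.integer(score > 0.5)
}

# unified fit/predict over both model families
model_ids <- function() {
  c("f1", "f2", "f3", "random_forest", "xgboost", "decision_tree",
    "lightgbm", "catboost")
}

fit_any <- function(train, model_id, seed = 1L) {
  if (model_id %in% c("f1", "f2", "f3")) {
    fit_threshold(train, model_id)
  } else {
    fit_multifeature(train, model_id, seed = seed)
  }
}

#' Stratified k-fold cross-validation of a BP-variation classifier
#'
#' Samples are partitioned into `k` folds stratified by label (preserving
#' the 1:1 balance within folds); the model — a single-feature threshold
#' classifier (`model_id` in `"f1"`, `"f2"`, `"f3"`) or a multi-feature
#' learner — is fit on the training folds only and evaluated on the held-out
#' fold with the six metrics.
#'
#' @param data Labeled (typically balanced) tibble with `f1`, `f2`, `f3`,
#'   `label`.
#' @param model_id See [fit_threshold()] and [fit_multifeature()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment and learner fits.
#'
#' @return An object of class `ppg_cv`: list with `folds` (per-fold metric
#'   tibble), `summary` (mean and sd per metric), `model_id`, `k`, `seed`,
#'   `fold_assignment`.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   f1 = rnorm(60), f2 = c(rnorm(30), rnorm(30, 3)), f3 = rnorm(60),
#'   label = rep(0:1, each = 30)
#' )
#' cv <- crossvalidate(d, "f2", k = 5, seed = 1)
#' glance(cv)
crossvalidate <- function(data, model_id, k = 10, seed = 1L) {
  y <- data$label
  n_min <- min(sum(y == 1), sum(y == 0))
  if (k > n_min) {
    stop("k = ", k, " exceeds the smaller class count (", n_min, ").", call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in c(0, 1)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  res <- purrr::map_dfr(seq_len(k), function(f) {
    train <- data[fold != f, ]
    test <- data[fold == f, ]
    m <- fit_any(train, model_id, seed = seed + f)
    pred <- predict(m, test, type = "class")
    score <- predict(m, test, type = "score")
    dplyr::bind_cols(tibble::tibble(fold = f),
                     evaluate_predictions(test$label, pred, score))
  })
  metric_cols <- c("acc", "auc", "mcc", "f1", "kappa", "auprc")
  summ <- tibble::tibble(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(res[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(res[[m]], na.rm = TRUE), numeric(1))
  )
  structure(
    list(folds = res, summary = summ, model_id = model_id, k = k,
         seed = as.integer(seed), fold_assignment = fold),
    class = "ppg_cv"
  )
}

#' @export
print.ppg_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation of `%s` (seed %d)\n", x$k, x$model_id, x$seed))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.ppg_cv <- function(x, ...) x$folds

#' @export
glance.ppg_cv <- function(x, ...) {
  wide <- stats::setNames(
    as.list(c(x$summary$mean, x$summary$sd)),
    c(paste0(x$summary$metric, "_mean"), paste0(x$summary$metric, "_sd"))
  )
  dplyr::bind_cols(tibble::tibble(model_id = x$model_id, k = x$k), tibble::as_tibble(wide))
}

#' @export
autoplot.ppg_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds, -"fold",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 0.8) +
    ggplot2::labs(title = sprintf("%d-fold CV, model `%s`", object$k, object$model_id),
                  x = NULL, y = "metric value") +
    ggplot2::theme_minimal()
}

#' Sweep the BP-change threshold from 5 to 15 mmHg
#'
#' For each change threshold, the aligned feature records are labeled,
#' balanced 1:1 and cross-validated with each requested model; thresholds
#' for which one class is empty are reported with `NA` metrics and a note
#' rather than fabricated.
#'
#' @param features_bp A `feature_set` with aligned BP columns (from
#'   [align_bp()]), or a `ppg_session` (preprocessed internally with window
#'   size `n`).
#' @param bp_kind `"sbp"`, `"dbp"` or `"mbp"`.
#' @param thresholds Integer thresholds in mmHg (default 5:15).
#' @param models Character vector of model ids.
#' @param n Template window size (used only when a session is supplied).
#' @param k CV folds.
#' @param seed Integer seed.
#' @param reference Labeling reference policy (see [label_delta()]).
#'
#' @return A tibble of class `ppg_sweep_report`: one row per
#'   (threshold, model) with `<metric>_mean` / `<metric>_sd` columns,
#'   `n_samples`, `note`, and a list-column `folds` of per-fold metrics.
#' @export
sweep_delta_bp <- function(features_bp, bp_kind = "mbp", thresholds = 5:15,
                           models = c("f1", "f2", "f3", "random_forest",
                                      "decision_tree"),
                           n = 5, k = 10, seed = 1L,
                           reference = "segment_start") {
  if (inherits(features_bp, "ppg_session")) {
    cyc <- preprocess_ppg(features_bp$ppg)
    features_bp <- align_bp(extract_features(cyc, n = n), features_bp)
  }
  grid <- tidyr::expand_grid(threshold = thresholds, model_id = models)
  out <- purrr::pmap_dfr(grid, function(threshold, model_id) {
    lab <- label_delta(features_bp, bp_kind = bp_kind, threshold = threshold,
                       reference = reference)
    base <- tibble::tibble(threshold = threshold, model_id = model_id,
                           bp_kind = bp_kind)
    if (sum(lab$label == 1) < k || sum(lab$label == 0) < k) {
      return(dplyr::bind_cols(base, tibble::tibble(
        n_samples = NA_integer_, note = "empty_or_too_small_class",
        folds = list(NULL)
      )))
    }
    bal <- balance_dataset(lab, seed = seed)
    cv <- crossvalidate(bal, model_id, k = k, seed = seed)
    g <- glance(cv)[-(1:2)]
    dplyr::bind_cols(base, g,
                     tibble::tibble(n_samples = nrow(bal), note = NA_character_,
                                    folds = list(cv$folds)))
  })
  class(out) <- c("ppg_sweep_report", class(out))
  out
}

#' Sweep the template window size (2 to 7 cycles)
#'
#' Re-runs feature extraction, labeling, balancing and cross-validation for
#' each template window size, then aggregates each metric's per-threshold
#' mean into a mean and standard deviation across the 5–15 mmHg thresholds —
#' the basis for choosing the best window size.
#'
#' @param session A `ppg_session`.
#' @param windows Integer window sizes in cycles (all must be >= 2; the
#'   single-cycle case is outside the protocol and rejected).
#' @inheritParams sweep_delta_bp
#'
#' @return A tibble: one row per (window, model) with `<metric>_mean` /
#'   `<metric>_sd` aggregated across thresholds, and a list-column
#'   `per_threshold` holding the underlying [sweep_delta_bp()] rows.
#' @export
sweep_window_size <- function(session, windows = 2:7, bp_kind = "mbp",
                              thresholds = 5:15, models = "random_forest",
                              k = 10, seed = 1L, reference = "segment_start") {
  if (any(windows < 2)) {
    stop("window sizes below 2 cycles are outside the protocol.", call. = FALSE)
  }
  cyc <- preprocess_ppg(session$ppg)
  metric_cols <- c("acc", "auc", "mcc", "f1", "kappa", "auprc")
  purrr::map_dfr(windows, function(w) {
    if (nrow(cyc) < w + 2) {
      warning("window ", w, " skipped: too few cycles.")
      return(tibble::tibble())
    }
    feats <- align_bp(extract_features(cyc, n = w), session)
    rep <- sweep_delta_bp(feats, bp_kind = bp_kind, thresholds = thresholds,
                          models = models, k = k, seed = seed,
                          reference = reference)
    purrr::map_dfr(unique(rep$model_id), function(m) {
      sub <- rep[rep$model_id == m & is.na(rep$note), ]
      agg <- stats::setNames(
        as.list(c(
          vapply(metric_cols, function(mc) mean(sub[[paste0(mc, "_mean")]]), numeric(1)),
          vapply(metric_cols, function(mc) stats::sd(sub[[paste0(mc, "_mean")]]), numeric(1))
        )),
        c(paste0(metric_cols, "_mean"), paste0(metric_cols, "_sd"))
      )
      dplyr::bind_cols(
        tibble::tibble(window = w, model_id = m, bp_kind = bp_kind,
                       n_thresholds = nrow(sub)),
        tibble::as_tibble(agg),
        tibble::tibble(per_threshold = list(sub))
      )
    })
  })
}

#' Plot a delta-BP threshold sweep report
#'
#' @param report A `ppg_sweep_report` from [sweep_delta_bp()].
#' @param metric Metric column to draw (default `"acc"`).
#' @return A ggplot object: metric mean (± sd ribbon) against the BP-change
#'   threshold, one line per model.
#' @export
autoplot.ppg_sweep_report <- function(object, metric = "acc", ...) {
  mcol <- paste0(metric, "_mean"); scol <- paste0(metric, "_sd")
  df <- object[!is.na(object[[mcol]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data[[mcol]],
                                   colour = .data$model_id, fill = .data$model_id)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                                      ymax = .data[[mcol]] + .data[[scol]]),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "BP-change threshold (mmHg)", y = paste(metric, "(CV mean)"),
                  colour = "model", fill = "model") +
    ggplot2::theme_minimal()
}
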