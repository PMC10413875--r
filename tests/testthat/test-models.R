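test_that("threshold fitting separates separable data in both directions", {
  d <- tibble::tibble(f2 = c(1, 2, 3, 4), label = c(0L, 0L, 1L, 1L))
  m <- fit_threshold(d, "f2")
  expect_equal(m$youden_j, 1)
  # any cut in [2, 3) separates under the strict > decision rule; the
  # tie-break picks the smallest such grid cut
  expect_gte(m$cut, 2); expect_lt(m$cut, 3)
  expect_equal(m$direction, "greater_is_positive")
  expect_equal(predict(m, d), c(0L, 0L, 1L, 1L))
  # anti-ordered labels flip the direction
  d2 <- tibble::tibble(f2 = c(1, 2, 3, 4), label = c(1L, 1L, 0L, 0L))
  m2 <- fit_threshold(d2, "f2")
  expect_equal(m2$youden_j, 1)
  expect_equal(m2$direction, "less_is_positive")
  expect_equal(predict(m2, d2), c(1L, 1L, 0L, 0L))
  expect_error(fit_threshold(tibble::tibble(f2 = rep(1, 4), label = c(0L, 0L, 1L, 1L)), "f2"),
               "constant")
})

test_that("threshold decisions are invariant under monotone feature transforms", {
  set.seed(10)
  d <- tibble::tibble(f1 = c(rnorm(30, 0), rnorm(30, 4)), label = rep(0:1, each = 30))
  m <- fit_threshold(d, "f1")
  d_t <- dplyr::mutate(d, f1 = exp(f1 / 2))
  m_t <- fit_threshold(d_t, "f1")
  expect_equal(predict(m, d), predict(m_t, d_t))
  expect_equal(m$youden_j, m_t$youden_j)
})

test_that("evaluation metrics match closed forms", {
  # perfect predictions with separated scores
  perf <- evaluate_predictions(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(unlist(perf), c(acc = 1, auc = 1, mcc = 1, f1 = 1, kappa = 1, auprc = 1))
  # all-positive predictions on a balanced set
  allpos <- evaluate_predictions(rep(0:1, each = 5), rep(1, 10), rep(0.9, 10))
  expect_equal(allpos$acc, 0.5)
  expect_equal(allpos$mcc, 0)
  expect_equal(allpos$kappa, 0)
  expect_equal(allpos$f1, 2 / 3)
  # confusion TP=3 FP=1 FN=2 TN=4
  y_true <- c(rep(1, 3), rep(0, 1), rep(1, 2), rep(0, 4))
  y_pred <- c(rep(1, 3), rep(1, 1), rep(0, 2), rep(0, 4))
  r <- evaluate_predictions(y_true, y_pred)
  expect_equal(r$acc, 0.7)
  expect_equal(r$f1, 2 / 3)
  expect_equal(r$mcc, 10 / sqrt(600), tolerance = 1e-9)
  # single-class truth: ranking metrics undefined
  expect_error(roc_auc(rep(1, 5), runif(5)), "single-class")
  expect_error(pr_auc(rep(0, 5), runif(5)), "single-class")
  expect_warning(evaluate_predictions(rep(1, 5), rep(1, 5)), "single-class")
})

test_that("ranking metrics agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:5) {
    y <- rep(0:1, each = 25)
    s <- rnorm(50, mean = y)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
    expect_equal(roc_auc(y, s), ref, tolerance = 1e-9)
  }
})

test_that("metrics stay within their defined ranges on random predictions", {
  set.seed(12)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    p <- sample(0:1, n, replace = TRUE)
    s <- runif(n)
    r <- evaluate_predictions(y, p, s)
    expect_true(r$acc >= 0 && r$acc <= 1)
    expect_true(r$auc >= 0 && r$auc <= 1)
    expect_true(r$f1 >= 0 && r$f1 <= 1)
    expect_true(r$auprc >= 0 && r$auprc <= 1)
    expect_true(r$mcc >= -1 && r$mcc <= 1)
    expect_true(r$kappa >= -1 && r$kappa <= 1)
  }
})

test_that("cross-validation partitions the data and is seed-reproducible", {
  d <- gaussian_features(50, seed = 13)
  cv <- crossvalidate(d, "f1", k = 10, seed = 2)
  expect_equal(nrow(cv$folds), 10)
  # every sample in exactly one test fold, folds stratified
  expect_equal(sort(unique(cv$fold_assignment)), 1:10)
  expect_equal(length(cv$fold_assignment), nrow(d))
  for (f in 1:10) {
    expect_equal(sum(cv$fold_assignment == f & d$label == 1), 5)
  }
  cv2 <- crossvalidate(d, "f1", k = 10, seed = 2)
  expect_identical(cv$folds, cv2$folds)
  expect_error(crossvalidate(d[1:12, ], "f1", k = 10), "class count")
  # tidy/glance accessors
  expect_equal(nrow(tidy(cv)), 10)
  g <- glance(cv)
  expect_true(all(c("acc_mean", "auc_mean", "kappa_sd") %in% names(g)))
})

test_that("threshold model approaches the Gaussian Bayes accuracy", {
  d <- gaussian_features(500, d_prime = 2, seed = 14)
  cv <- crossvalidate(d, "f1", k = 10, seed = 3)
  acc <- cv$summary$mean[cv$summary$metric == "acc"]
  expect_gt(acc, pnorm(1) - 0.04)
  expect_lt(acc, pnorm(1) + 0.04)
})

test_that("permuted labels drive every model to chance accuracy", {
  d <- gaussian_features(250, d_prime = 2, seed = 15)
  set.seed(16)
  d$label <- sample(d$label)
  for (m in c("f1", "decision_tree")) {
    cv <- crossvalidate(d, m, k = 10, seed = 4)
    acc <- cv$summary$mean[cv$summary$metric == "acc"]
    expect_gt(acc, 0.5 - 0.07)
    expect_lt(acc, 0.5 + 0.07)
  }
})

test_that("multi-feature learners fit, predict, and fail loudly when absent", {
  set.seed(17)
  d <- tibble::tibble(
    f1 = c(rnorm(30, 0), rnorm(30, 6)), f2 = rnorm(60), f3 = rnorm(60),
    label = rep(0:1, each = 30)
  )
  # linearly separable: decision tree reaches training accuracy 1
  dt <- fit_multifeature(d, "decision_tree")
  expect_equal(mean(predict(dt, d) == d$label), 1)
  for (m in c("random_forest", "xgboost")) {
    fit <- fit_multifeature(d, m, seed = 7)
    sc <- predict(fit, d, type = "score")
    expect_true(all(sc >= 0 & sc <= 1))
    expect_gt(mean(predict(fit, d) == d$label), 0.95)
  }
  # seeding contract on the stochastic learner
  cva <- crossvalidate(d, "random_forest", k = 5, seed = 8)
  cvb <- crossvalidate(d, "random_forest", k = 5, seed = 8)
  expect_identical(cva$folds, cvb$folds)
  expect_error(fit_multifeature(d, "boosted_stump"), "valid ids")
  expect_error(fit_multifeature(d, "lightgbm"), "not installed")
  expect_error(fit_multifeature(d, "catboost"), "not installed")
})

test_that("delta-BP sweep emits one report row per threshold and model", {
  ses <- quiet_session(duration = 120, noise_sd = 0.05, drift_amp = 0.2, seed = 20)
  feats <- align_bp(extract_features(preprocess_ppg(ses$ppg), n = 5), ses)
  rep <- sweep_delta_bp(feats, thresholds = c(5, 10, 15),
                        models = c("f2", "decision_tree"), seed = 5)
  expect_equal(nrow(rep), 6)
  expect_true(all(!is.na(rep$acc_mean) | !is.na(rep$note)))
  # metrics monotone trend: higher threshold no harder than the lowest
  f2rows <- rep[rep$model_id == "f2", ]
  expect_gte(f2rows$acc_mean[f2rows$threshold == 15],
             f2rows$acc_mean[f2rows$threshold == 5] - 0.05)
})

test_that("window-size sweep aggregates thresholds and rejects window 1", {
  ses <- quiet_session(duration = 120, noise_sd = 0.05, drift_amp = 0.2, seed = 21)
  expect_error(sweep_window_size(ses, windows = 1:3), "outside the protocol")
  sw <- sweep_window_size(ses, windows = c(3, 5), thresholds = c(5, 10, 15),
                          models = "decision_tree", seed = 6)
  expect_equal(nrow(sw), 2)
  expect_equal(sw$n_thresholds, c(3, 3))
  # aggregate equals direct recomputation from the per-threshold rows
  for (i in 1:2) {
    per <- sw$per_threshold[[i]]
    expect_equal(sw$acc_mean[i], mean(per$acc_mean))
    expect_equal(sw$acc_sd[i], sd(per$acc_mean))
  }
})
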