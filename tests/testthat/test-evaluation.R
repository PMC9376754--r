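# Independent references for the metric suite.
oracle_metrics <- function(truth, pred) {
  tp <- sum(truth & pred); tn <- sum(!truth & !pred)
  fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  sens <- tp / (tp + fn)
  list(sens = sens, spec = tn / (tn + fp), prec = prec,
       acc = (tp + tn) / length(truth),
       f1 = if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens))
}
oracle_auc <- function(truth, scores) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

separable_table <- function(n = 60) {
  set.seed(31)
  target <- rep(c(0, 1), each = n / 2)
  ft <- data.frame(test_id = as.character(seq_len(n)),
                   patient_id = sprintf("P%02d", rep(1:(n / 4), each = 2)),
                   target = target)
  for (col in feature_model_columns()) {
    ft[[col]] <- target * 10 + rnorm(n, sd = 0.1)
  }
  ft$adf_pvalue <- 0.5
  ft
}

test_that("record-level splits are stratified at the target proportions", {
  set.seed(1)
  ft <- separable_table(100)
  ft$target <- rep(c(1, 0), c(40, 60))
  for (s in 1:20) {
    sp <- split_data(ft, "by_test", 0.2, seed = s)
    expect_equal(nrow(sp$test), 20)
    expect_equal(sum(sp$test$target), 8)
    expect_equal(nrow(sp$train) + nrow(sp$test), 100)
    expect_length(intersect(sp$train$test_id, sp$test$test_id), 0)
  }
})

test_that("patient-grouped splits never share a patient across sides", {
  ft <- study_features()$features
  for (s in 1:50) {
    sp <- split_data(ft, "by_patient", 0.2, seed = s)
    expect_length(intersect(unique(sp$train$patient_id),
                            unique(sp$test$patient_id)), 0)
    expect_equal(nrow(sp$train) + nrow(sp$test), nrow(ft))
    # a multi-test patient travels whole
    counts <- table(ft$patient_id)
    big <- names(counts)[which.max(counts)]
    side <- c(sum(sp$train$patient_id == big), sum(sp$test$patient_id == big))
    expect_true(any(side == 0))
    expect_equal(sum(side), unname(counts[big]))
  }
})

test_that("metric suite matches confusion-matrix arithmetic and pairwise AUC", {
  m <- compute_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  for (v in c("sensitivity", "specificity", "precision", "accuracy", "f1", "auc")) {
    expect_equal(m[[v]], 1)
  }
  m2 <- compute_metrics(c(1, 1, 1, 1, 0, 0), rep(1, 6))
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$specificity, 0)
  expect_equal(m2$precision, 2 / 3)
  # all-tied scores: AUC is exactly one half
  expect_equal(compute_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0),
                               rep(0.3, 4))$auc, 0.5)
  # no positive predictions: precision and F1 fall to 0 by convention
  m3 <- compute_metrics(c(1, 0, 1, 0), rep(0, 4), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(m3$precision, 0)
  expect_equal(m3$f1, 0)
  # single-class truth: AUC undefined
  expect_true(is.na(compute_metrics(c(1, 1), c(1, 0), c(0.5, 0.4))$auc))

  set.seed(55)
  for (i in 1:100) {
    n <- sample(10:80, 1)
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) truth[1:2] <- c(0, 1)
    pred <- rbinom(n, 1, 0.5)
    scores <- round(rnorm(n), 1)   # coarse scores force ties
    got <- compute_metrics(truth, pred, scores)
    ref <- oracle_metrics(truth, pred)
    expect_equal(got$sensitivity, ref$sens, tolerance = 1e-9)
    expect_equal(got$specificity, ref$spec, tolerance = 1e-9)
    expect_equal(got$precision, ref$prec, tolerance = 1e-9)
    expect_equal(got$accuracy, ref$acc, tolerance = 1e-9)
    expect_equal(got$f1, ref$f1, tolerance = 1e-9)
    expect_equal(got$auc, oracle_auc(truth, scores), tolerance = 1e-9)
  }
})

test_that("rank-based AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:20) {
    truth <- rbinom(40, 1, 0.5); truth[1:2] <- c(0, 1)
    scores <- round(rnorm(40), 1)
    got <- compute_metrics(truth, as.integer(scores > 0), scores)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("cross-validation separates the separable and stays null on permuted labels", {
  ft <- separable_table(60)
  set.seed(12)
  for (m in list(model_spec("logistic_regression"), model_spec("svm", "linear"))) {
    expect_gte(crossval_accuracy(m, ft, 5, "by_test"), 0.95)
  }
  # permuted labels: accuracy hovers near chance
  set.seed(1234)
  ft_null <- separable_table(200)
  ft_null$target <- sample(ft_null$target)
  for (col in feature_model_columns()) ft_null[[col]] <- rnorm(200)
  acc <- crossval_accuracy(model_spec("logistic_regression"), ft_null, 5)
  expect_gte(acc, 0.35); expect_lte(acc, 0.65)
  # leave-one-out boundary case runs
  small <- separable_table(12)
  expect_no_error(crossval_accuracy(model_spec("svm", "linear"), small,
                                    cv_folds = 12, "by_test"))
})

test_that("runs are reproducible from their seeds and bounded in [0, 1]", {
  ft <- study_features()$features
  cfg <- experiment_config(n_repetitions = 2, base_seed = 314)
  for (mode in c("by_test", "by_patient")) {
    a <- run_single(ft, cfg, cfg$models$svm_rbf, 1, mode, "zeros")
    b <- run_single(ft, cfg, cfg$models$svm_rbf, 1, mode, "zeros")
    expect_identical(a, b)
    vals <- unlist(a)
    expect_true(all(vals[!is.na(vals)] >= 0 & vals[!is.na(vals)] <= 1))
  }
  a1 <- run_single(ft, cfg, cfg$models$random_forest, 1, "by_test", "zeros")
  a2 <- run_single(ft, cfg, cfg$models$random_forest, 2, "by_test", "zeros")
  expect_false(identical(a1, a2))
})

test_that("the grid has 20 cells, averages exactly, and logs every run", {
  ft <- study_features()$features
  cfg <- experiment_config(n_repetitions = 1, base_seed = 99,
                           models = default_models()[c("logistic_regression",
                                                       "svm_linear")])
  expect_equal(experiment_size(experiment_config())$n_cells, 20)
  expect_equal(experiment_size(experiment_config())$n_runs, 6000)

  log_path <- withr::local_tempfile(fileext = ".jsonl")
  mt <- run_experiment_grid(ft, cfg, log_path = log_path)
  expect_equal(nrow(mt), 2 * 2 * 2)
  expect_equal(length(readLines(log_path)), nrow(mt) * 1)

  # with one repetition the cell mean equals the single run
  one <- run_single(ft, cfg, cfg$models$logistic_regression, 1,
                    "by_test", "zeros")
  row <- mt[mt$split_mode == "by_test" & mt$impute_scheme == "zeros" &
              mt$model == "logistic_regression", ]
  expect_equal(row$f1_mean, one$f1)
  expect_equal(row$auc_mean, one$auc)
  expect_equal(row$cv_accuracy_mean, one$cv_accuracy)

  # averaged metric equals the arithmetic mean of per-repetition metrics
  cfg3 <- experiment_config(n_repetitions = 3, base_seed = 99,
                            models = default_models()["svm_linear"],
                            split_modes = "by_test", impute_schemes = "zeros")
  mt3 <- run_experiment_grid(ft, cfg3)
  per_rep <- vapply(1:3, function(r) {
    run_single(ft, cfg3, cfg3$models$svm_linear, r, "by_test", "zeros")$f1
  }, numeric(1))
  expect_equal(mt3$f1_mean, mean(per_rep), tolerance = 1e-12)
})

test_that("result CSVs mirror the per-variant layout", {
  ft <- study_features()$features
  cfg <- experiment_config(n_repetitions = 1, base_seed = 5,
                           models = default_models()["svm_linear"])
  mt <- run_experiment_grid(ft, cfg)
  dir <- withr::local_tempdir()
  paths <- write_metrics_tables(mt, dir)
  files <- list.files(dir, pattern = "^results_")
  expect_length(files, 4)   # one per input variant
  tab <- read.csv(file.path(dir, files[1]))
  expect_equal(names(tab), c("model", "cv", "spec", "sens", "prec", "rec",
                             "acc", "f1", "auc"))
})
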