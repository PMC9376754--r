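# The repeated-resampling classification experiment.
#
# Grid: split mode (by test / by patient) x imputation scheme (zeros /
# ratio means) x classifier, each cell repeated over seeded 80/20
# resamplings with 5-fold cross-validation on the training side, metrics
# averaged over repetitions. Patient-grouped splitting keeps all tests of a
# patient on one side, which is the leakage-free evaluation; record-level
# splitting is retained for the comparison it enables.

#' Experiment configuration
#'
#' @param split_modes Split schemes to run (`"by_test"`, `"by_patient"`).
#' @param impute_schemes Imputation schemes to run (`"zeros"`,
#'   `"ratio_mean"`).
#' @param models Named list of [model_spec()]s (default: the five standard
#'   classifiers).
#' @param test_fraction Held-out fraction per resampling (default 0.2).
#' @param cv_folds Cross-validation folds on the training side (default 5).
#' @param n_repetitions Resampling repetitions per cell (default 300).
#' @param base_seed Base RNG seed; repetition `r` seeds its split with
#'   `base_seed + r` and its model fit with `base_seed + 1e6 + r`.
#' @param fit_on_all Compatibility switch: fit imputation and normalisation
#'   statistics on all rows before splitting instead of on training rows
#'   only. Default `FALSE` (leakage-free).
#' @param include_adf Include the ADF p-value among model inputs.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(split_modes = c("by_test", "by_patient"),
                              impute_schemes = c("zeros", "ratio_mean"),
                              models = default_models(),
                              test_fraction = 0.2, cv_folds = 5L,
                              n_repetitions = 300L, base_seed = 20220128L,
                              fit_on_all = FALSE, include_adf = FALSE) {
  split_modes <- match.arg(split_modes, c("by_test", "by_patient"),
                           several.ok = TRUE)
  impute_schemes <- match.arg(impute_schemes, c("zeros", "ratio_mean"),
                              several.ok = TRUE)
  stopifnot(test_fraction > 0, test_fraction < 1, cv_folds >= 2,
            n_repetitions >= 1, length(models) >= 1)
  if (is.null(names(models))) {
    names(models) <- vapply(models, `[[`, character(1), "label")
  }
  structure(list(split_modes = split_modes, impute_schemes = impute_schemes,
                 models = models, test_fraction = test_fraction,
                 cv_folds = as.integer(cv_folds),
                 n_repetitions = as.integer(n_repetitions),
                 base_seed = as.integer(base_seed),
                 fit_on_all = isTRUE(fit_on_all),
                 include_adf = isTRUE(include_adf)),
            class = "experiment_config")
}

#' Size of the experiment design
#'
#' @param config An [experiment_config()].
#' @return List with `n_cells` (input-variant x model combinations) and
#'   `n_runs` (cells times repetitions).
#' @export
experiment_size <- function(config) {
  n_cells <- length(config$split_modes) * length(config$impute_schemes) *
    length(config$models)
  list(n_cells = n_cells, n_runs = n_cells * config$n_repetitions)
}

#' Stratified train/test split, record-level or patient-grouped
#'
#' `by_test`: rows are sampled within each class at the target proportion.
#' `by_patient`: whole patients are assigned to one side; within each
#' patient-level class, patients are taken in random order into the test
#' side until its row count reaches the target fraction of that class's
#' rows, always leaving at least one patient of the class in training.
#' Both classes are kept on both sides whenever the data allow it; if a
#' record-level resampling still loses a class, it is redrawn (up to
#' `max_tries`).
#'
#' @param table A feature table with `patient_id` and `target` columns.
#' @param mode `"by_test"` or `"by_patient"`.
#' @param test_fraction Held-out fraction of rows.
#' @param seed Optional integer; when given, seeds the RNG first.
#' @param max_tries Redraw limit for degenerate record-level splits.
#' @return List with `train` and `test` data.frames.
#' @export
split_data <- function(table, mode = c("by_test", "by_patient"),
                       test_fraction = 0.2, seed = NULL, max_tries = 100L) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(table) >= 4)
  if (length(unique(table$target)) < 2L) {
    stop("both classes must be present before splitting")
  }
  if (mode == "by_test") {
    for (try in seq_len(max_tries)) {
      test_idx <- unlist(lapply(split(seq_len(nrow(table)), table$target),
                                function(idx) {
        k <- round(length(idx) * test_fraction)
        k <- max(1L, min(k, length(idx) - 1L))
        sample(idx, k)
      }), use.names = FALSE)
      train <- table[-test_idx, , drop = FALSE]
      test <- table[test_idx, , drop = FALSE]
      if (length(unique(train$target)) == 2L &&
          length(unique(test$target)) == 2L) {
        return(list(train = train, test = test))
      }
    }
    stop("could not draw a record-level split with both classes on both sides")
  }
  # by_patient: patients carry a single class (patient-level outcome)
  pat <- unique(table[c("patient_id", "target")])
  if (anyDuplicated(pat$patient_id)) {
    stop("by_patient splitting requires one class per patient")
  }
  rows_per_pat <- table(table$patient_id)
  test_patients <- character(0)
  for (cls in unique(pat$target)) {
    pats <- sample(pat$patient_id[pat$target == cls])
    n_rows_cls <- sum(rows_per_pat[pats])
    target_rows <- test_fraction * n_rows_cls
    if (length(pats) < 2L) next   # lone-class patient stays in training
    got <- 0
    for (p in pats) {
      if (got >= target_rows) break
      if (length(test_patients[test_patients %in% pats]) >= length(pats) - 1L)
        break   # keep >= 1 patient of this class in training
      test_patients <- c(test_patients, p)
      got <- got + rows_per_pat[[p]]
    }
  }
  in_test <- table$patient_id %in% test_patients
  if (!any(in_test) || all(in_test)) {
    stop("patient-grouped split left one side empty")
  }
  list(train = table[!in_test, , drop = FALSE],
       test = table[in_test, , drop = FALSE])
}

make_cv_folds <- function(table, cv_folds, mode, max_tries = 100L) {
  n <- nrow(table)
  for (try in seq_len(max_tries)) {
    fold <- integer(n)
    if (mode == "by_patient") {
      pat <- unique(table[c("patient_id", "target")])
      for (cls in unique(pat$target)) {
        pats <- sample(pat$patient_id[pat$target == cls])
        pf <- rep_len(seq_len(cv_folds), length(pats))
        for (j in seq_along(pats)) {
          fold[table$patient_id == pats[j]] <- pf[j]
        }
      }
    } else {
      # shuffle within class, then deal one fold cycle across the class
      # blocks so every fold is filled even when cv_folds approaches n
      ord <- unlist(lapply(unique(table$target), function(cls) {
        sample(which(table$target == cls))
      }), use.names = FALSE)
      fold[ord] <- rep_len(seq_len(cv_folds), n)
    }
    ok <- all(vapply(seq_len(cv_folds), function(j) {
      sum(fold == j) > 0L &&
        length(unique(table$target[fold != j])) == 2L
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("could not build cross-validation folds with both classes in every training part")
}

#' Cross-validated accuracy on the training side
#'
#' Stratified folds; under patient-grouped splitting the folds group
#' patients too, so the fold structure matches the outer split. Folds whose
#' training part loses a class are redrawn.
#'
#' @param spec A [model_spec()].
#' @param train Training feature table (imputed and normalised).
#' @param cv_folds Number of folds.
#' @param mode Active split mode, `"by_test"` or `"by_patient"`.
#' @param include_adf Whether the ADF p-value is a model input.
#' @return Mean held-fold accuracy.
#' @export
crossval_accuracy <- function(spec, train, cv_folds = 5L, mode = "by_test",
                              include_adf = FALSE) {
  stopifnot(nrow(train) >= cv_folds)
  cols <- feature_model_columns(include_adf)
  fold <- make_cv_folds(train, cv_folds, mode)
  accs <- vapply(seq_len(cv_folds), function(j) {
    tr <- train[fold != j, , drop = FALSE]
    ho <- train[fold == j, , drop = FALSE]
    fit <- fit_model(spec, tr[, cols, drop = FALSE], tr$target)
    pred <- predict_scores(fit, ho)
    mean(pred$label == ho$target)
  }, numeric(1))
  mean(accs)
}

#' Binary classification metric suite
#'
#' Sensitivity (= recall), specificity, precision, accuracy, F1 and AUC for
#' the positive class 1. Zero-denominator conventions: precision and F1 are
#' 0 when no positive predictions exist; sensitivity/specificity are `NA`
#' when the truth lacks the corresponding class. AUC is the rank statistic
#' over continuous decision scores with ties counted one half, and is `NA`
#' for single-class truth.
#'
#' @param truth Integer 0/1 true labels.
#' @param pred Integer 0/1 predicted labels.
#' @param scores Numeric decision scores (larger = more positive).
#' @return Named list of metrics, class `ccep_metrics`.
#' @export
compute_metrics <- function(truth, pred, scores = NULL) {
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth == 1 & pred == 1)
  tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  acc <- (tp + tn) / length(truth)
  f1 <- if (is.na(sens) || prec + sens == 0) 0
        else 2 * prec * sens / (prec + sens)
  auc <- NA_real_
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(truth))
    n1 <- sum(truth == 1); n0 <- sum(truth == 0)
    if (n1 > 0 && n0 > 0) {
      r <- rank(scores)   # average ranks: ties count one half
      auc <- (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  structure(list(specificity = spec, sensitivity = sens, precision = prec,
                 recall = sens, accuracy = acc, f1 = f1, auc = auc),
            class = "ccep_metrics")
}

METRIC_NAMES <- c("cv_accuracy", "specificity", "sensitivity", "precision",
                  "recall", "accuracy", "f1", "auc")

#' One seeded resampling run
#'
#' Splits, fits imputation and normalisation statistics on the training side
#' (or on all rows when `fit_on_all`), cross-validates on the training side,
#' fits on the full training side, and evaluates on the held-out side.
#' Fully reproducible: repetition `r` uses `base_seed + r` for the split and
#' fold structure and `base_seed + 1e6 + r` for the model fit.
#'
#' @param table Raw (un-imputed) feature table.
#' @param config An [experiment_config()].
#' @param model A [model_spec()].
#' @param repetition Repetition index (1-based).
#' @param split_mode,impute_scheme The cell being run.
#' @return Named list: the [compute_metrics()] suite plus `cv_accuracy`.
#' @export
run_single <- function(table, config, model, repetition,
                       split_mode = config$split_modes[1],
                       impute_scheme = config$impute_schemes[1]) {
  cols <- feature_model_columns(config$include_adf)
  set.seed(config$base_seed + repetition)
  parts <- split_data(table, split_mode, config$test_fraction)
  stats_src <- if (config$fit_on_all) table else parts$train
  imp <- if (impute_scheme == "ratio_mean") fit_impute_stats(stats_src)
         else NULL
  train <- impute_missing(parts$train, impute_scheme, imp)
  test <- impute_missing(parts$test, impute_scheme, imp)
  norm <- fit_normalizer(if (config$fit_on_all)
                           impute_missing(table, impute_scheme, imp)
                         else train, cols)
  train <- apply_normalizer(train, norm)
  test <- apply_normalizer(test, norm)

  cv <- crossval_accuracy(model, train, config$cv_folds, split_mode,
                          config$include_adf)
  set.seed(config$base_seed + 1000000L + repetition)
  fit <- fit_model(model, train[, cols, drop = FALSE], train$target)
  pred <- predict_scores(fit, test)
  m <- compute_metrics(test$target, pred$label, pred$score)
  c(list(cv_accuracy = cv), unclass(m))
}

cell_runs <- function(table, config, model, split_mode, impute_scheme,
                      jobs = 1L) {
  one <- function(r) {
    unlist(run_single(table, config, model, r, split_mode, impute_scheme))
  }
  reps <- seq_len(config$n_repetitions)
  if (jobs > 1L && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(reps, one, mc.cores = jobs)
  } else {
    res <- lapply(reps, one)
  }
  do.call(rbind, res)
}

#' Run the full experiment grid
#'
#' Iterates split mode x imputation scheme x model; each cell is repeated
#' `n_repetitions` times with per-repetition seeds and its metrics are
#' averaged over repetitions (undefined metrics, e.g. AUC on single-class
#' held-out sets, are excluded from the average). Because every repetition
#' is seeded independently, results are identical at any `jobs` setting.
#'
#' @param table Raw (un-imputed) feature table.
#' @param config An [experiment_config()].
#' @param log_path Optional JSON-lines run log: one record per run with the
#'   cell, seeds, hyperparameters and metrics.
#' @param jobs Repetition-level parallelism (default 1).
#' @return A `ccep_metrics_table` data.frame: one row per cell with
#'   per-metric means and standard deviations.
#' @export
run_experiment_grid <- function(table, config = experiment_config(),
                                log_path = NULL, jobs = 1L) {
  grid <- expand.grid(model = names(config$models),
                      impute_scheme = config$impute_schemes,
                      split_mode = config$split_modes,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("split_mode", "impute_scheme", "model")]
  log_con <- NULL
  if (!is.null(log_path)) {
    log_con <- file(log_path, "w")
    on.exit(close(log_con))
  }
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    model <- config$models[[grid$model[g]]]
    runs <- cell_runs(table, config, model, grid$split_mode[g],
                      grid$impute_scheme[g], jobs)
    if (!is.null(log_con)) {
      for (r in seq_len(nrow(runs))) {
        rec <- list(split_mode = grid$split_mode[g],
                    impute_scheme = grid$impute_scheme[g],
                    model = model$label, repetition = r,
                    seed_split = config$base_seed + r,
                    seed_fit = config$base_seed + 1000000L + r,
                    hyperparameters = model$hyperparameters,
                    metrics = as.list(runs[r, ]))
        writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                    na = "null", digits = NA), log_con)
      }
    }
    means <- colMeans(runs, na.rm = TRUE)
    sds <- apply(runs, 2, stats::sd, na.rm = TRUE)
    row <- data.frame(split_mode = grid$split_mode[g],
                      impute_scheme = grid$impute_scheme[g],
                      model = model$label,
                      n_repetitions = config$n_repetitions)
    for (m in METRIC_NAMES) {
      row[[paste0(m, "_mean")]] <- means[[m]]
      row[[paste0(m, "_sd")]] <- sds[[m]]
    }
    out[[g]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ccep_metrics_table", "data.frame")
  res
}

#' Write per-variant results CSVs
#'
#' One CSV per (split mode, imputation scheme) input variant, rows = models,
#' columns = mean CV accuracy, specificity, sensitivity, precision, recall,
#' accuracy, F1 and AUC.
#'
#' @param metrics_table A `ccep_metrics_table`.
#' @param out_dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_metrics_tables <- function(metrics_table, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  variants <- unique(metrics_table[c("split_mode", "impute_scheme")])
  for (i in seq_len(nrow(variants))) {
    sel <- metrics_table$split_mode == variants$split_mode[i] &
      metrics_table$impute_scheme == variants$impute_scheme[i]
    sub <- metrics_table[sel, c("model", paste0(METRIC_NAMES, "_mean"))]
    names(sub) <- c("model", "cv", "spec", "sens", "prec", "rec", "acc",
                    "f1", "auc")
    p <- file.path(out_dir, sprintf("results_%s_%s.csv",
                                    variants$split_mode[i],
                                    variants$impute_scheme[i]))
    utils::write.csv(sub, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
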