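# Classifier wrappers: random forest, logistic regression, and SVMs with
# linear / radial / polynomial kernels, behind one fit/score interface.
# Hyperparameters are the backing libraries' documented defaults, pinned
# here and recorded in the run log; features are already min-max normalised
# so the SVM's internal rescaling is disabled.

#' Classifier specification
#'
#' @param family `"random_forest"`, `"logistic_regression"` or `"svm"`.
#' @param kernel For SVMs: `"linear"`, `"rbf"` or `"poly"`.
#' @param hyperparameters Named list overriding the pinned defaults.
#' @return A list of class `model_spec` with resolved hyperparameters.
#' @export
model_spec <- function(family = c("random_forest", "logistic_regression", "svm"),
                       kernel = NULL, hyperparameters = list()) {
  family <- match.arg(family)
  if (family == "svm") {
    kernel <- match.arg(kernel, c("linear", "rbf", "poly"))
  } else if (!is.null(kernel)) {
    stop("kernel applies to SVM models only")
  }
  defaults <- switch(family,
    random_forest = list(ntree = 500L),
    logistic_regression = list(),
    svm = list(cost = 1, degree = 3L, coef0 = 0, gamma = NULL))  # gamma: 1/p
  hp <- utils::modifyList(defaults, hyperparameters)
  label <- if (family == "svm") paste0("svm_", kernel) else family
  structure(list(family = family, kernel = kernel, hyperparameters = hp,
                 label = label), class = "model_spec")
}

#' The five classifiers of the default experiment
#' @return Named list of [model_spec()]s.
#' @export
default_models <- function() {
  specs <- list(model_spec("random_forest"),
                model_spec("logistic_regression"),
                model_spec("svm", "linear"),
                model_spec("svm", "rbf"),
                model_spec("svm", "poly"))
  names(specs) <- vapply(specs, `[[`, character(1), "label")
  specs
}

svm_kernel_name <- function(kernel) {
  switch(kernel, linear = "linear", rbf = "radial", poly = "polynomial")
}

#' Fit a classifier on a feature matrix
#'
#' @param spec A [model_spec()].
#' @param x Data.frame of numeric features.
#' @param y Integer 0/1 targets.
#' @return A fitted model wrapper of class `ccep_fit`.
#' @export
fit_model <- function(spec, x, y) {
  stopifnot(inherits(spec, "model_spec"), nrow(x) == length(y))
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  yf <- factor(y, levels = c(0, 1))
  hp <- spec$hyperparameters
  fit <- switch(spec$family,
    random_forest = randomForest::randomForest(x, yf, ntree = hp$ntree),
    logistic_regression = {
      d <- cbind(x, .target = y)
      suppressWarnings(stats::glm(.target ~ ., data = d, family = stats::binomial()))
    },
    svm = {
      gamma <- if (is.null(hp$gamma)) 1 / ncol(x) else hp$gamma
      e1071::svm(as.matrix(x), yf, kernel = svm_kernel_name(spec$kernel),
                 cost = hp$cost, degree = hp$degree, coef0 = hp$coef0,
                 gamma = gamma, scale = FALSE)
    })
  structure(list(spec = spec, fit = fit, features = names(x)),
            class = "ccep_fit")
}

#' Predict labels and continuous decision scores
#'
#' Scores are oriented so that larger values indicate the positive
#' (deterioration) class: class-1 probability for the random forest and
#' logistic regression, signed decision value for the SVMs.
#'
#' @param object A `ccep_fit`.
#' @param newdata Data.frame with the training feature columns.
#' @return List with `label` (integer 0/1) and `score` (numeric).
#' @export
predict_scores <- function(object, newdata) {
  stopifnot(inherits(object, "ccep_fit"))
  x <- newdata[, object$features, drop = FALSE]
  spec <- object$spec
  if (spec$family == "random_forest") {
    score <- unname(stats::predict(object$fit, x, type = "prob")[, "1"])
    label <- as.integer(as.character(stats::predict(object$fit, x)))
  } else if (spec$family == "logistic_regression") {
    # rank-deficient designs occur legitimately on small clustered splits
    score <- unname(suppressWarnings(
      stats::predict(object$fit, newdata = x, type = "response")))
    label <- as.integer(score > 0.5)
  } else {
    pred <- stats::predict(object$fit, as.matrix(x), decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # column name "a/b": positive decision values favour class a
    parts <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
    score <- if (parts[1] == "1") dv[, 1] else -dv[, 1]
    score <- unname(score)
    label <- as.integer(as.character(pred))
  }
  list(label = label, score = score)
}
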