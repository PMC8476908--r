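# Classical ML pipeline: Pearson feature filtering, patient-level split,
# leave-one-patient-out grid search, and LDC / SVM / KNN / XGBoost training
# for the five classification tasks.

TASKS <- c("type1", "type2_lr", "type2_si", "type2_ap", "type3")
MODEL_KINDS <- c("ldc", "svm", "knn", "xgboost")
LABEL_COLS <- c("isocenter_mm", "type1", "type2_lr", "type2_si", "type2_ap",
                "type3")
META_COLS <- c("patient_id", "serial", LABEL_COLS)

feature_cols <- function(features) {
  setdiff(names(features), META_COLS)
}

#' Pearson correlation feature filter
#'
#' Keeps the features whose absolute Pearson correlation with the (integer
#' coded) task label reaches `threshold`; zero-variance features are always
#' dropped. Fit this on training samples only to avoid leakage.
#'
#' @param features a feature tibble from [build_feature_matrix()].
#' @param task one of `"type1"`, `"type2_lr"`, `"type2_si"`, `"type2_ap"`,
#'   `"type3"`.
#' @param threshold minimum `|r|` to keep a feature (default 0.1).
#' @return The filtered tibble; the kept feature names are in
#'   `attr(, "kept")`.
#' @export
pearson_filter <- function(features, task = "type1", threshold = 0.1) {
  task <- match.arg(task, TASKS)
  fc <- feature_cols(features)
  if (nrow(features) < 2) stop("need at least 2 samples", call. = FALSE)
  y <- as.numeric(features[[task]])
  keep <- vapply(fc, function(f) {
    x <- features[[f]]
    if (stats::sd(x) == 0) return(FALSE)
    abs(stats::cor(x, y)) >= threshold
  }, logical(1))
  if (!any(keep))
    stop("all features dropped by the Pearson filter; lower `threshold`",
         call. = FALSE)
  out <- features[, c(intersect(META_COLS, names(features)), fc[keep])]
  attr(out, "kept") <- fc[keep]
  out
}

#' Patient-level train/test split
#'
#' Randomly assigns whole patients (all their error positions) to the
#' training or testing side in a 80/20 ratio — 32 versus 8 patients at the
#' study size of 40 — so no patient contributes samples to both sides.
#'
#' @param x a cohort or feature tibble with a `patient_id` column, or a
#'   character vector of patient ids.
#' @param seed RNG seed for the assignment.
#' @param test_frac held-out fraction (default 0.2).
#' @return A list with character vectors `train` and `test`.
#' @export
split_by_patient <- function(x, seed = 1L, test_frac = 0.2) {
  ids <- if (is.character(x)) unique(x) else unique(x$patient_id)
  n <- length(ids)
  if (n < 2) stop("need at least 2 patients to split", call. = FALSE)
  n_test <- max(1L, round(test_frac * n))
  test <- local_seed(seed, sample(ids, n_test))
  list(train = setdiff(ids, test), test = test)
}

#' Hyperparameter grids
#'
#' The search spaces used by the leave-one-patient-out grid search:
#' KNN neighbours 1-10; SVM kernels linear and RBF with
#' C in \{0.01, 0.1, 1, 10\} and (RBF only) gamma in
#' \{0.001, 0.01, 0.1, 1\}; LDC a single canonical solver; XGBoost 10-100
#' boosting rounds (step 10) with maximum depth 3-10 for the binary tasks
#' and 100-250 rounds (step 10) with depth 3-10 for the 8-way task.
#'
#' @param model_kind `"ldc"`, `"svm"`, `"knn"` or `"xgboost"`.
#' @param task task id (the XGBoost grid depends on it).
#' @return A tibble with one row per grid point.
#' @export
model_grid <- function(model_kind = MODEL_KINDS, task = "type1") {
  model_kind <- match.arg(model_kind)
  task <- match.arg(task, TASKS)
  switch(model_kind,
    ldc = tibble::tibble(solver = "svd"),
    knn = tibble::tibble(k = 1:10),
    svm = dplyr::bind_rows(
      tidyr::expand_grid(kernel = "linear", C = c(0.01, 0.1, 1, 10),
                         gamma = NA_real_),
      tidyr::expand_grid(kernel = "rbf", C = c(0.01, 0.1, 1, 10),
                         gamma = c(0.001, 0.01, 0.1, 1))),
    xgboost = tidyr::expand_grid(
      nrounds = if (task == "type3") seq(100L, 250L, 10L)
                else seq(10L, 100L, 10L),
      max_depth = 3:10))
}

# Standardise columns by training-set statistics (KNN is scale sensitive).
scale_train_stats <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}

apply_scale <- function(X, st) sweep(sweep(X, 2, st$mu), 2, st$sd, "/")

fit_one <- function(model_kind, params, X, y) {
  y <- factor(y)
  if (nlevels(y) < 2)
    stop("degenerate training labels: a single class", call. = FALSE)
  fit <- switch(model_kind,
    ldc = {
      # LDA is affine invariant, so standardise (keeps lda's tolerance
      # checks on a common scale) and drop features with essentially no
      # pooled within-class variance, which lda rejects outright
      st <- scale_train_stats(X)
      Xs <- apply_scale(X, st)
      gm <- rowsum(Xs, y) / as.vector(table(y))
      within_sd <- sqrt(colMeans((Xs - gm[as.character(y), , drop = FALSE])^2))
      keep <- within_sd > 1e-4
      if (!any(keep)) stop("no usable features for LDA", call. = FALSE)
      # collinearity warnings are expected for correlated radiomics features
      fit <- suppressWarnings(MASS::lda(Xs[, keep, drop = FALSE],
                                        grouping = y))
      list(fit = fit, st = st, keep = keep)
    },
    svm = {
      if (params$kernel == "linear")
        e1071::svm(X, y, kernel = "linear", cost = params$C,
                   probability = TRUE)
      else
        e1071::svm(X, y, kernel = "radial", cost = params$C,
                   gamma = params$gamma, probability = TRUE)
    },
    knn = {
      st <- scale_train_stats(X)
      list(X = apply_scale(X, st), y = y, k = params$k, st = st)
    },
    xgboost = {
      xgboost::xgboost(X, y, nrounds = params$nrounds,
                       max_depth = params$max_depth,
                       nthread = 1, verbosity = 0)
    })
  list(kind = model_kind, fit = fit, levels = levels(y), params = params)
}

# Predict classes and per-class score matrix (columns = class levels).
predict_one <- function(model, X) {
  lv <- model$levels
  scores <- switch(model$kind,
    ldc = {
      Xs <- apply_scale(X, model$fit$st)[, model$fit$keep, drop = FALSE]
      p <- stats::predict(model$fit$fit, Xs)$posterior
      p[, lv, drop = FALSE]
    },
    svm = {
      p <- attr(stats::predict(model$fit, X, probability = TRUE),
                "probabilities")
      p[, lv, drop = FALSE]
    },
    knn = {
      Xs <- apply_scale(X, model$fit$st)
      pr <- class::knn(model$fit$X, Xs, model$fit$y, k = model$fit$k,
                       prob = TRUE)
      win <- attr(pr, "prob")
      p <- matrix(0, nrow(Xs), length(lv), dimnames = list(NULL, lv))
      for (i in seq_len(nrow(Xs))) {
        p[i, as.character(pr[i])] <- win[i]
        rest <- setdiff(lv, as.character(pr[i]))
        p[i, rest] <- (1 - win[i]) / length(rest)
      }
      p
    },
    xgboost = {
      pr <- stats::predict(model$fit, X)
      if (is.matrix(pr)) {
        p <- pr[, lv, drop = FALSE]
      } else {
        # binary: probability of the second factor level
        p <- cbind(1 - pr, pr)
        colnames(p) <- lv
      }
      p
    })
  list(pred = lv[max.col(scores)], scores = scores)
}

#' Grid-search tuning with leave-one-patient-out CV
#'
#' For every grid point, fits the model on all but one training patient and
#' scores the held-out patient, cycling through every training patient; the
#' grid point with the highest mean accuracy (ties: first listed) is refit
#' on the full training set.
#'
#' @param features training-set feature tibble (already Pearson-filtered).
#' @param task task id.
#' @param model_kind `"ldc"`, `"svm"`, `"knn"` or `"xgboost"`.
#' @param grid a grid tibble as from [model_grid()].
#' @return An object of class `epid_model`: the refit model with the chosen
#'   hyperparameters, selected feature names and CV accuracy table.
#' @export
tune_and_train <- function(features, task = "type1",
                           model_kind = MODEL_KINDS,
                           grid = NULL) {
  task <- match.arg(task, TASKS)
  model_kind <- match.arg(model_kind)
  if (is.null(grid)) grid <- model_grid(model_kind, task)
  stopifnot(nrow(grid) >= 1)
  pats <- unique(features$patient_id)
  if (length(pats) < 3) stop("need at least 3 training patients", call. = FALSE)
  fc <- feature_cols(features)
  X <- as.matrix(features[, fc])
  y <- features[[task]]

  cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- vapply(pats, function(p) {
      hold <- features$patient_id == p
      fit <- fit_one(model_kind, grid[g, ], X[!hold, , drop = FALSE],
                     y[!hold])
      sum(predict_one(fit, X[hold, , drop = FALSE])$pred == y[hold])
    }, numeric(1))
    sum(correct) / length(y)
  }, numeric(1))

  best <- which.max(cv_acc) # ties: first grid point
  final <- fit_one(model_kind, grid[best, ], X, y)
  structure(list(kind = model_kind, task = task, fit = final,
                 params = grid[best, ], features = fc,
                 cv = dplyr::bind_cols(grid, tibble::tibble(cv_accuracy = cv_acc))),
            class = "epid_model")
}

#' @export
print.epid_model <- function(x, ...) {
  cat(sprintf("<epid_model %s, task %s>\n", x$kind, x$task))
  cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                         collapse = ", "), "\n")
  cat(sprintf("  %d features, CV accuracy %.3f\n", length(x$features),
              max(x$cv$cv_accuracy)))
  invisible(x)
}

#' @describeIn tune_and_train predict with a tuned model; returns a tibble
#'   of predicted classes and per-class score columns.
#' @param object an `epid_model`.
#' @param newdata feature tibble containing the model's feature columns.
#' @param ... unused.
#' @export
predict.epid_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features])
  out <- predict_one(object$fit, X)
  scores <- tibble::as_tibble(as.data.frame(out$scores))
  names(scores) <- paste0("score_", colnames(out$scores))
  dplyr::bind_cols(tibble::tibble(pred = as.integer(out$pred)), scores)
}

#' Tidy a tuned model's grid search
#'
#' @param x an `epid_model`.
#' @param ... unused.
#' @return The grid tibble with the leave-one-patient-out `cv_accuracy` of
#'   every point.
#' @export
tidy.epid_model <- function(x, ...) x$cv

#' @export
glance.epid_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, task = x$task,
                 n_features = length(x$features),
                 cv_accuracy = max(x$cv$cv_accuracy))
}

#' End-to-end classification experiment
#'
#' Runs the full pipeline on a cohort for one (input configuration, task,
#' model) triple: patient-level 80/20 split, Pearson filtering fit on the
#' training patients, leave-one-patient-out grid search, refit, and
#' held-out prediction.
#'
#' @param cohort a [generate_cohort()] tibble; ignored when `features` is
#'   given.
#' @param ml_config `"ml1"` (DD features), `"ml2"` (SSIM component
#'   features) or `"ml3"` (both).
#' @param task task id.
#' @param model_kind model kind.
#' @param seed seed for the patient split.
#' @param features optional precomputed [build_feature_matrix()] output
#'   (avoids recomputing maps across experiments).
#' @param pearson_threshold minimum `|r|` for the feature filter.
#' @param grid optional grid override.
#' @return An `epid_experiment`: list with the trained `model`, the
#'   per-sample `predictions` tibble (truth, prediction, scores), the split,
#'   and ids.
#' @export
run_experiment <- function(cohort = NULL, ml_config = "ml3", task = "type1",
                           model_kind = "ldc", seed = 1L, features = NULL,
                           pearson_threshold = 0.1, grid = NULL) {
  task <- match.arg(task, TASKS)
  if (is.null(features)) features <- build_feature_matrix(cohort, ml_config)
  split <- split_by_patient(features, seed)
  train <- features[features$patient_id %in% split$train, ]
  test <- features[features$patient_id %in% split$test, ]
  train_f <- pearson_filter(train, task, pearson_threshold)
  model <- tune_and_train(train_f, task, model_kind, grid)
  pred <- predict.epid_model(model, test)
  predictions <- dplyr::bind_cols(
    test[, c("patient_id", "serial")],
    tibble::tibble(truth = as.integer(test[[task]])), pred)
  structure(list(model = model, predictions = predictions, split = split,
                 ml_config = ml_config, task = task,
                 model_kind = model_kind, seed = seed),
            class = "epid_experiment")
}

#' @export
print.epid_experiment <- function(x, ...) {
  cat(sprintf("<epid_experiment %s / %s / %s>\n", x$ml_config, x$task,
              x$model_kind))
  cat(sprintf("  train %d / test %d patients; held-out accuracy %.3f\n",
              length(x$split$train), length(x$split$test),
              accuracy(x$predictions)))
  invisible(x)
}

#' @export
glance.epid_experiment <- function(x, ...) {
  binary <- length(unique(x$predictions$truth)) == 2 &&
    all(x$predictions$truth %in% 1:2)
  tibble::tibble(
    ml_config = x$ml_config, task = x$task, model = x$model_kind,
    accuracy = accuracy(x$predictions),
    auc = if (binary) roc_auc(x$predictions)$auc else NA_real_)
}

#' @export
tidy.epid_experiment <- function(x, ...) x$predictions
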