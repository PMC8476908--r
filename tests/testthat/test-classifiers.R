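# Feature filtering, splitting, grid search and the end-to-end experiment.

test_that("pearson_filter keeps correlated features and drops constants", {
  n_pat <- 4; per <- 4
  lab <- rep(c(1L, 1L, 2L, 2L), n_pat)
  feats <- toy_features(
    n_pat, per,
    features = list(f_perfect = as.numeric(lab),
                    f_constant = rep(3, 16),
                    f_noise = withr::with_seed(1, rnorm(16))),
    labels = list(type1 = lab, type2_lr = lab, type2_si = lab,
                  type2_ap = lab, type3 = lab, isocenter_mm = lab))
  out <- pearson_filter(feats, "type1", threshold = 0.3)
  expect_true("f_perfect" %in% attr(out, "kept"))
  expect_false("f_constant" %in% attr(out, "kept"))

  # r = 0.8944 for (1,2,3,4) against labels (1,1,2,2)
  f2 <- toy_features(2, 2,
                     features = list(f = c(1, 2, 3, 4)),
                     labels = list(type1 = c(1L, 1L, 2L, 2L),
                                   type2_lr = c(1L, 1L, 2L, 2L),
                                   type2_si = c(1L, 1L, 2L, 2L),
                                   type2_ap = c(1L, 1L, 2L, 2L),
                                   type3 = c(1L, 1L, 2L, 2L),
                                   isocenter_mm = c(0, 0, 4, 4)))
  expect_equal(abs(stats::cor(c(1, 2, 3, 4), c(1, 1, 2, 2))), 0.8944,
               tolerance = 1e-4)
  expect_true("f" %in% attr(pearson_filter(f2, "type1", 0.3), "kept"))
  expect_error(pearson_filter(f2, "type1", 0.99), "lower")
})

test_that("patient-level splits are 80/20, disjoint and deterministic", {
  ids40 <- sprintf("P%03d", 1:40)
  sp <- split_by_patient(ids40, seed = 1)
  expect_length(sp$train, 32)
  expect_length(sp$test, 8)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_by_patient(ids40, seed = 1))
  expect_false(identical(sp$test, split_by_patient(ids40, seed = 2)$test))

  sp10 <- split_by_patient(sprintf("P%02d", 1:10), seed = 3)
  expect_length(sp10$train, 8)
  expect_length(sp10$test, 2)

  expect_error(split_by_patient("P01"), "at least 2")
})

test_that("hyperparameter grids match the published search spaces", {
  expect_equal(model_grid("knn")$k, 1:10)

  svm <- model_grid("svm")
  expect_equal(nrow(svm), 4 + 16)
  expect_true(all(is.na(svm$gamma[svm$kernel == "linear"])))
  expect_equal(sort(unique(svm$C)), c(0.01, 0.1, 1, 10))
  expect_equal(sort(unique(svm$gamma[svm$kernel == "rbf"])),
               c(0.001, 0.01, 0.1, 1))

  xg1 <- model_grid("xgboost", "type1")
  expect_equal(sort(unique(xg1$nrounds)), seq(10L, 100L, 10L))
  expect_equal(sort(unique(xg1$max_depth)), 3:10)
  xg3 <- model_grid("xgboost", "type3")
  expect_equal(sort(unique(xg3$nrounds)), seq(100L, 250L, 10L))
  expect_equal(nrow(xg3), 16 * 8)

  expect_equal(nrow(model_grid("ldc")), 1)
})

# Separable toy features: the label is recoverable from f1, plus nuisance.
separable_features <- function(n_pat = 6, per = 9, seed = 5) {
  n <- n_pat * per
  lab <- rep(rep(1:2, length.out = per), n_pat)
  withr::with_seed(seed, {
    f1 <- lab * 10 + rnorm(n, 0, 0.5)
    f2 <- rnorm(n)
    f3 <- 0.2 * lab + rnorm(n, 0, 1)
  })
  toy_features(n_pat, per,
               features = list(f1 = f1, f2 = f2, f3 = f3),
               labels = list(type1 = as.integer(lab),
                             type2_lr = as.integer(lab),
                             type2_si = as.integer(lab),
                             type2_ap = as.integer(lab),
                             type3 = as.integer(lab),
                             isocenter_mm = as.numeric(lab)))
}

test_that("tuning selects from the grid and a 1-NN model memorises", {
  feats <- separable_features()
  m <- tune_and_train(feats, "type1", "knn")
  expect_true(m$params$k %in% 1:10)
  expect_equal(nrow(m$cv), 10)

  m1 <- tune_and_train(feats, "type1", "knn",
                       grid = tibble::tibble(k = 1L))
  pred <- predict(m1, feats)
  expect_equal(mean(pred$pred == feats$type1), 1) # training memorisation

  expect_error(tune_and_train(feats[feats$patient_id %in%
                                      unique(feats$patient_id)[1:2], ],
                              "type1", "knn"), "3 training patients")

  degenerate <- separable_features()
  degenerate$type1 <- 1L
  expect_error(tune_and_train(degenerate, "type1", "ldc"), "single class")
})

test_that("each model kind trains and predicts on separable data", {
  feats <- separable_features(n_pat = 6)
  for (kind in c("ldc", "svm", "knn", "xgboost")) {
    grid <- switch(kind,
                   svm = tibble::tibble(kernel = "linear", C = 1,
                                        gamma = NA_real_),
                   xgboost = tibble::tibble(nrounds = 10L, max_depth = 3L),
                   NULL)
    m <- tune_and_train(feats, "type1", kind, grid = grid)
    pred <- predict(m, feats)
    expect_gt(mean(pred$pred == feats$type1), 0.9)
    # score columns cover both classes and behave like probabilities
    expect_true(all(c("score_1", "score_2") %in% names(pred)))
    expect_equal(pred$score_1 + pred$score_2, rep(1, nrow(pred)),
                 tolerance = 1e-6)
  }
})

test_that("the experiment filters features on training patients only", {
  feats <- separable_features(n_pat = 8)
  # a feature that is pure noise in every patient: must never be selected
  feats$f_noise2 <- withr::with_seed(9, rnorm(nrow(feats)))
  ex <- run_experiment(features = feats, task = "type1", model_kind = "ldc",
                       seed = 2, pearson_threshold = 0.4)
  expect_true(all(ex$model$features %in% c("f1", "f3")))
  expect_false("f_noise2" %in% ex$model$features)
  # no test patient contributed to training
  expect_length(intersect(unique(ex$predictions$patient_id),
                          ex$split$train), 0)
  # experiment is deterministic given the seed
  ex2 <- run_experiment(features = feats, task = "type1",
                        model_kind = "ldc", seed = 2,
                        pearson_threshold = 0.4)
  expect_equal(ex$predictions, ex2$predictions)
})

test_that("permuted labels give no skill beyond the majority class", {
  feats <- separable_features(n_pat = 10, per = 27)
  # destroy the association, keeping the label marginal
  feats$type1 <- withr::with_seed(13, sample(feats$type1))
  # threshold 0 keeps all non-constant features: the filter itself would
  # (rightly) drop everything once the labels are shuffled
  ex <- run_experiment(features = feats, task = "type1", model_kind = "ldc",
                       seed = 4, pearson_threshold = 0)
  n <- nrow(ex$predictions)
  maj <- max(table(ex$predictions$truth)) / n
  expect_lte(accuracy(ex$predictions),
             maj + 3.5 * sqrt(maj * (1 - maj) / n))
})
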