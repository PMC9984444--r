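make_bench_cohorts <- function(n_train = 250, n_test = 120, seed = 1, ...) {
  simulate_cohorts(sim_config(n_train = n_train, n_test = n_test,
                              seed = seed, ...))
}

single_config_specs <- function(folds = 5, seed = 1) {
  list(
    model_spec("AB", grid = list(n_estimators = 60, learning_rate = 0.5),
               folds = folds, seed = seed),
    model_spec("LR", grid = list(C = 1), folds = folds, seed = seed),
    model_spec("DT", grid = list(max_depth = 3, min_leaf = 10),
               folds = folds, seed = seed),
    model_spec("GB", grid = list(n_estimators = 80, learning_rate = 0.1,
                                 max_depth = 2), folds = folds, seed = seed)
  )
}

test_that("feature building reproduces dose features and one-hot covariates", {
  ch <- toy_cohort(list(dvh(60, 1), dvh(40, 1)), c(1, 0))
  x <- build_features(ch)
  expect_equal(unname(x[, "mean_dose"]), c(60, 40))
  expect_equal(unname(x[, "max_dose"]), c(60, 40))
  expect_equal(nrow(x), 2L)

  sim <- make_bench_cohorts(n_train = 25, n_test = 10, seed = 2)
  xf <- build_features(sim$train)
  expect_equal(nrow(xf), 25L)
  expect_true(all(c("mean_dose", "max_dose", "age", "chemo_yes") %in%
                    colnames(xf)))
  expect_true(all(xf[, "chemo_yes"] %in% c(0, 1)))
  expect_equal(unname(xf[, "chemo_yes"]),
               as.numeric(sim$train$patients$chemo == "yes"))
})

test_that("a single-configuration grid makes tuning a no-op", {
  sim <- make_bench_cohorts(n_train = 60, n_test = 10, seed = 3)
  x <- build_features(sim$train)
  y <- sim$train$patients$toxicity
  tf <- tune_and_fit(model_spec("LR", grid = list(C = 0.5)), x, y)
  expect_equal(tf$hyper$C, 0.5)
  expect_true(is.na(tf$validation_auc))
  p <- tf$predict(x)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("logistic regression separates linearly separable features perfectly", {
  set.seed(4)
  x <- cbind(f1 = c(rnorm(40, -3), rnorm(40, 3)), f2 = rnorm(80))
  y <- rep(c(0, 1), each = 40)
  tf <- tune_and_fit(model_spec("LR", grid = list(C = 100), folds = 5), x, y)
  expect_equal(roc_auc(tf$predict(x), y), 1.0)
})

test_that("every backend fits and predicts calibrated-range probabilities", {
  sim <- make_bench_cohorts(n_train = 120, n_test = 60, seed = 5)
  x <- build_features(sim$train)
  y <- sim$train$patients$toxicity
  xt <- build_features(sim$test)
  for (sp in single_config_specs()) {
    tf <- tune_and_fit(sp, x, y)
    p <- tf$predict(xt)
    expect_length(p, nrow(xt))
    expect_true(all(p >= 0 & p <= 1))
    # every model must beat coin-flip ranking on this dose-driven cohort
    expect_gt(roc_auc(p, sim$test$patients$toxicity), 0.55)
  }
})

test_that("label permutation drives cross-validated AUC to chance", {
  sim <- make_bench_cohorts(n_train = 80, n_test = 10, seed = 6)
  x <- build_features(sim$train)
  y <- sim$train$patients$toxicity
  aucs <- vapply(1:10, function(s) {
    yp <- withr::with_seed(1000 + s, sample(y))
    tf <- tune_and_fit(model_spec("LR", grid = list(C = c(0.1, 1)),
                                  folds = 5, seed = s), x, yp)
    tf$validation_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("tuning refuses fold counts exceeding the minority class", {
  x <- cbind(a = rnorm(30), b = rnorm(30))
  y <- c(rep(1, 5), rep(0, 25))
  expect_error(
    tune_and_fit(model_spec("LR", grid = list(C = c(0.1, 1)), folds = 10), x, y),
    "lower folds")
})

test_that("benchmark fills one row per model plus LKB with in-range metrics", {
  sim <- make_bench_cohorts(n_train = 300, n_test = 150, seed = 7)
  lkb <- lkb_fit(sim$train, "differential_evolution", seed = 1,
                 control = list(maxiter = 80))
  specs <- list(
    model_spec("AB", grid = list(n_estimators = c(30, 100),
                                 learning_rate = c(0.1, 0.5)), folds = 5),
    model_spec("LR", grid = list(C = c(0.01, 1)), folds = 5),
    model_spec("DT", grid = list(max_depth = c(1, 2, 3),
                                 min_leaf = c(10, 20)), folds = 5),
    model_spec("GB", grid = list(n_estimators = c(50, 100),
                                 learning_rate = c(0.05, 0.1),
                                 max_depth = c(1, 2)), folds = 5))
  rep <- benchmark(sim$train, sim$test, specs, lkb, seed = 1)
  expect_equal(nrow(rep), 5L)
  expect_setequal(rep$model, c("LKB", "AB", "LR", "DT", "GB"))
  for (col in c("accuracy_train", "accuracy_test", "auc_train", "auc_test",
                "brier_train", "brier_test")) {
    expect_true(all(rep[[col]] >= 0 & rep[[col]] <= 1), label = col)
  }
  expect_false(any(rep$failed))
  # on a pure-LKB cohort every model beats the constant-prevalence predictor
  y_te <- sim$test$patients$toxicity
  base <- mean(y_te) * (1 - mean(y_te))
  expect_true(all(rep$brier_test <= base + 0.01))
})

test_that("a model that cannot be tuned is reported failed, not fatal", {
  sim <- make_bench_cohorts(n_train = 120, n_test = 60, seed = 8)
  lkb <- lkb_fit(sim$train, "differential_evolution", seed = 1,
                 control = list(maxiter = 60))
  specs <- list(
    model_spec("LR", grid = list(C = 1), folds = 5),
    # folds far beyond the minority class: stratification must fail
    model_spec("DT", grid = list(max_depth = c(2, 3), min_leaf = 5),
               folds = 200)
  )
  expect_warning(
    rep <- benchmark(sim$train, sim$test, specs, lkb, seed = 1),
    "failed to fit")
  expect_equal(nrow(rep), 3L)
  expect_true(rep$failed[rep$model == "DT"])
  expect_false(rep$failed[rep$model == "LR"])
})

test_that("benchmark refuses overlapping cohorts and unconverged LKB fits", {
  sim <- make_bench_cohorts(n_train = 40, n_test = 20, seed = 9)
  lkb <- lkb_fit(sim$train, "differential_evolution", seed = 1,
                 control = list(maxiter = 40))
  expect_error(benchmark(sim$train, sim$train, single_config_specs(), lkb),
               "share patient ids")
  bad <- lkb
  bad$converged <- FALSE
  expect_error(benchmark(sim$train, sim$test, single_config_specs(), bad),
               "converge")
})

test_that("benchmark reports serialize to CSV and JSON", {
  sim <- make_bench_cohorts(n_train = 80, n_test = 40, seed = 10)
  lkb <- lkb_fit(sim$train, "differential_evolution", seed = 1,
                 control = list(maxiter = 40))
  rep <- benchmark(sim$train, sim$test,
                   list(model_spec("LR", grid = list(C = 1))), lkb, seed = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_benchmark(rep, csv, js)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 2L)
  parsed <- jsonlite::read_json(js)
  expect_true(all(c("seed", "hyper", "table") %in% names(parsed)))
})
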