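#' Classifier specification for the benchmark
#'
#' A model identity, its hyperparameter search grid and the cross-validation
#' settings used to tune it.
#'
#' @param model_id One of `"AB"` (AdaBoost), `"LR"` (logistic regression),
#'   `"DT"` (decision tree), `"GB"` (gradient boosting).
#' @param grid Named list of candidate values per hyperparameter; defaults
#'   to [default_grid()]. Every named tunable must have at least one
#'   candidate.
#' @param folds Number of stratified cross-validation folds (default 20);
#'   must be at least 2 and no larger than the minority-class count of the
#'   training set at tuning time.
#' @param seed Integer seed for fold assignment.
#' @return A `model_spec` object.
#' @export
model_spec <- function(model_id, grid = default_grid(model_id),
                       folds = 20L, seed = 1L) {
  ml_backend(model_id)  # validates the id
  if (!is.list(grid) || length(grid) == 0L ||
      any(!nzchar(names(grid))) || any(vapply(grid, length, integer(1)) == 0L))
    stop("grid must be a named list with at least one candidate per tunable")
  if (folds < 2L) stop("folds must be >= 2")
  structure(list(model_id = model_id, grid = grid,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "model_spec")
}

#' Assemble the patients-by-features table of a cohort
#'
#' Default feature set: mean dose and maximum dose (highest positive-volume
#' bin) of each patient's DVH, followed by any covariates in the cohort
#' table. Categorical covariates are one-hot encoded (first level, in sorted
#' order, dropped as reference). Column order is fixed: dose features first,
#' then covariates in table order.
#'
#' @param ch An [cohort()] object.
#' @return Numeric matrix, one row per patient, with named columns.
#' @export
build_features <- function(ch) {
  stopifnot(inherits(ch, "ntcp_cohort"))
  mats <- list(
    mean_dose = vapply(ch$dvhs, mean_dose, numeric(1)),
    max_dose = vapply(ch$dvhs, max_dose, numeric(1))
  )
  cov <- cohort_covariates(ch)
  for (nm in names(cov)) {
    col <- cov[[nm]]
    if (all(is.na(col)))
      stop(sprintf("covariate '%s' has all-missing values", nm))
    if (is.numeric(col)) {
      mats[[nm]] <- col
    } else {
      lev <- sort(unique(as.character(col)))
      for (l in lev[-1L])
        mats[[paste0(nm, "_", l)]] <- as.numeric(col == l)
    }
  }
  x <- do.call(cbind, mats)
  rownames(x) <- as.character(ch$patients$patient_id)
  x
}

# deterministic stratified fold assignment; every fold gets both classes or
# the caller is told to lower the fold count
stratified_folds <- function(y, k, seed) {
  if (k > min(sum(y == 1), sum(y == 0)))
    stop(sprintf(
      "stratification error: %d folds exceed the minority class count (%d); lower folds",
      k, min(sum(y == 1), sum(y == 0))))
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Tune a classifier by cross-validated ROC-AUC and refit
#'
#' Exhaustive grid search maximizing the mean validation-fold ROC-AUC over
#' stratified folds, followed by a refit of the winning configuration on the
#' full training set. A single-configuration grid skips cross-validation
#' (tuning is a no-op). Deterministic per `spec$seed`. Ties in mean AUC go to
#' the earlier configuration in grid order.
#'
#' @param spec A [model_spec()].
#' @param x Training feature matrix (from [build_features()], possibly
#'   ComBat-corrected).
#' @param y Binary training labels; both classes must be present.
#' @return A list: `model_id`, fitted `handle`, chosen `hyper`,
#'   `validation_auc` (NA for a single-config grid), `tuning_time` and
#'   `fitting_time` in seconds, and the function `predict(newx)`.
#' @export
tune_and_fit <- function(spec, x, y) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(x)
  if (length(unique(y)) < 2L)
    stop("training labels must contain both classes")
  be <- ml_backend(spec$model_id)
  configs <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  t0 <- proc.time()[["elapsed"]]
  val_auc <- NA_real_
  if (nrow(configs) == 1L) {
    best <- as.list(configs[1L, , drop = FALSE])
  } else {
    fold <- stratified_folds(y, spec$folds, spec$seed)
    scores <- vapply(seq_len(nrow(configs)), function(ci) {
      hy <- as.list(configs[ci, , drop = FALSE])
      aucs <- vapply(seq_len(spec$folds), function(f) {
        tr <- fold != f
        h <- be$fit(x[tr, , drop = FALSE], y[tr], hy, seed = spec$seed + ci)
        p <- be$predict(h, x[!tr, , drop = FALSE])
        roc_auc(pmin(pmax(p, 0), 1), y[!tr])
      }, numeric(1))
      mean(aucs)
    }, numeric(1))
    best <- as.list(configs[which.max(scores), , drop = FALSE])
    val_auc <- max(scores)
  }
  tuning_time <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  handle <- be$fit(x, y, best, seed = spec$seed)
  fitting_time <- proc.time()[["elapsed"]] - t0
  list(
    model_id = spec$model_id,
    handle = handle,
    hyper = best,
    validation_auc = val_auc,
    tuning_time = tuning_time,
    fitting_time = fitting_time,
    predict = function(newx) {
      p <- be$predict(handle, as.matrix(newx))
      pmin(pmax(p, 0), 1)
    }
  )
}

score_row <- function(p_train, y_train, p_test, y_test) {
  c(accuracy_train = accuracy(p_train, y_train),
    accuracy_test = accuracy(p_test, y_test),
    auc_train = roc_auc(p_train, y_train),
    auc_test = roc_auc(p_test, y_test),
    brier_train = brier(p_train, y_train),
    brier_test = brier(p_test, y_test))
}

#' Benchmark the LKB model against tuned classifiers
#'
#' Fills the standard comparison table: per model (LKB plus every spec),
#' classification accuracy at threshold 0.5, ROC-AUC and Brier score on
#' both the training and the testing split, with tuning and fitting
#' wall-clock times.
#'
#' ML features are assembled with [build_features()] and, by default,
#' ComBat-harmonized across the two centres before tuning (fitted on the
#' union of train and test features, batch = centre; only continuous
#' columns are corrected). The LKB arm consumes raw DVHs: a whole
#' dose-volume curve cannot be fed through ComBat, which is precisely the
#' versatility asymmetry the comparison probes.
#'
#' A classifier that fails to fit is reported as a failed row rather than
#' aborting the run.
#'
#' @param train,test Disjoint [cohort()] objects.
#' @param specs List of [model_spec()] objects.
#' @param lkb A converged [lkb_fit()] result providing the LKB row.
#' @param combat Apply ComBat harmonization to the ML features
#'   (default `TRUE`).
#' @param seed Integer seed (recorded; per-model seeds derive from it).
#' @return A `benchmark_report`: data frame with one row per model
#'   (specs + LKB), metric columns for both splits, timing columns, a
#'   `failed` flag, and attributes `hyper` (chosen hyperparameters) and
#'   `seed`.
#' @export
benchmark <- function(train, test, specs, lkb, combat = TRUE, seed = 1L) {
  stopifnot(inherits(train, "ntcp_cohort"), inherits(test, "ntcp_cohort"),
            inherits(lkb, "lkb_fit"))
  if (length(intersect(train$patients$patient_id, test$patients$patient_id)))
    stop("train and test cohorts share patient ids")
  if (!lkb$converged)
    stop("the supplied LKB fit did not converge; refit before benchmarking")
  if (!all(vapply(specs, inherits, logical(1), what = "model_spec")))
    stop("specs must be a list of model_spec objects")

  y_train <- train$patients$toxicity
  y_test <- test$patients$toxicity
  x_train <- build_features(train)
  x_test <- build_features(test)

  if (combat) {
    xall <- rbind(x_train, x_test)
    batch <- c(as.character(train$patients$batch),
               as.character(test$patients$batch))
    continuous <- names(which(apply(xall, 2L, function(v)
      length(unique(v)) > 2L)))
    if (length(unique(batch)) >= 2L && length(continuous) >= 1L) {
      cm <- combat_fit(xall[, continuous, drop = FALSE], batch)
      corrected <- combat_apply(cm, xall[, continuous, drop = FALSE], batch)
      xall[, continuous] <- corrected
      x_train <- xall[seq_len(nrow(x_train)), , drop = FALSE]
      x_test <- xall[-seq_len(nrow(x_train)), , drop = FALSE]
    }
  }

  rows <- list()
  hypers <- list()

  # LKB row: NTCP probabilities from the fitted parameters on raw DVHs
  p_tr <- ntcp(cohort_gmd(train, lkb$params$n), lkb$params)
  p_te <- ntcp(cohort_gmd(test, lkb$params$n), lkb$params)
  rows[["LKB"]] <- c(score_row(p_tr, y_train, p_te, y_test),
                     tuning_time = NA_real_, fitting_time = lkb$elapsed)
  hypers[["LKB"]] <- unclass(lkb$params)

  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sp$seed <- sp$seed + as.integer(seed)
    id <- sp$model_id
    res <- tryCatch({
      tf <- tune_and_fit(sp, x_train, y_train)
      r <- c(score_row(tf$predict(x_train), y_train,
                       tf$predict(x_test), y_test),
             tuning_time = tf$tuning_time, fitting_time = tf$fitting_time)
      hypers[[id]] <- tf$hyper
      r
    }, error = function(e) {
      warning(sprintf("model %s failed to fit: %s", id, conditionMessage(e)))
      structure(rep(NA_real_, 8),
                names = c("accuracy_train", "accuracy_test", "auc_train",
                          "auc_test", "brier_train", "brier_test",
                          "tuning_time", "fitting_time"))
    })
    rows[[id]] <- res
  }

  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(model = names(rows), out)
  rownames(out) <- NULL
  out$failed <- is.na(out$brier_test)
  attr(out, "hyper") <- hypers
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("benchmark_report", class(out))
  out
}

#' Write a benchmark report as CSV and JSON
#'
#' @param report A [benchmark()] result.
#' @param path_csv,path_json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_benchmark <- function(report, path_csv = NULL, path_json = NULL) {
  stopifnot(inherits(report, "benchmark_report"))
  if (!is.null(path_csv))
    utils::write.csv(as.data.frame(report), path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(
      list(seed = attr(report, "seed"),
           hyper = attr(report, "hyper"),
           table = as.data.frame(report)),
      path_json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}
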