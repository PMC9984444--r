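#' Multi-start convergence sweep of the local LKB fitter
#'
#' Samples `n_starts` initial parameter triples uniformly over the bounds
#' box from a seeded generator, runs the local quasi-Newton fitter from
#' each, and classifies every run into one of three disjoint outcomes:
#' \describe{
#'   \item{failed}{the fit did not converge (optimizer failure or a
#'     non-finite loss);}
#'   \item{nonpredictive}{the fit converged but its test-set ROC-AUC is
#'     below `predictive_threshold`;}
#'   \item{predictive}{the remainder.}
#' }
#' This is the desk-scale analogue of a large multi-start study of the
#' model's convergence pathology: on a non-convex loss surface the local
#' gradient direction depends on the start, so a fraction of starts fails
#' or lands in poorly predictive basins while seeded global optimizers do
#' not. Predictiveness is judged on the model's actual predictions, i.e.
#' probabilities clipped to `[eps, 1 - eps]` exactly as in the fitting
#' loss: a start stranded on a clipped plateau (every prediction at the
#' clip) emits constant probabilities, whose all-tied ROC-AUC of 0.5 marks
#' it non-predictive.
#'
#' Runtime is estimated from the first few fits; a sweep projected to
#' exceed `budget_s` seconds is refused unless `force = TRUE`.
#'
#' @param train,test Disjoint [cohort()] objects; fits use `train`,
#'   predictiveness is judged on `test`.
#' @param n_starts Number of initial points (default 1000).
#' @param bounds Parameter box ([lkb_bounds()]).
#' @param predictive_threshold Test ROC-AUC below which a converged fit
#'   counts as non-predictive (default 0.7).
#' @param seed Integer seed; the sweep is deterministic per seed.
#' @param budget_s Runtime budget in seconds for the refusal check
#'   (default 3600).
#' @param eps Probability clipping constant used for the test-set
#'   predictions (default `1e-15`, matching [cohort_log_loss()]).
#' @param force Run even if the projected runtime exceeds the budget.
#' @param starts Optional matrix of initial points (columns `n`, `m`,
#'   `d50`) overriding uniform sampling, e.g. to force a single known-good
#'   start.
#' @return A `sweep_result`: counts and outcome fractions (summing to 1),
#'   `best_loss` over the sweep, min/median/max of test ROC-AUC over
#'   converged fits, the seed, and a per-start data frame `records` with
#'   columns `start_n`, `start_m`, `start_d50`, `converged`, `loss`,
#'   `test_auc`, `classification`.
#' @export
run_sweep <- function(train, test, n_starts = 1000L,
                      bounds = lkb_bounds(), predictive_threshold = 0.7,
                      seed = 1L, budget_s = 3600, force = FALSE,
                      starts = NULL, eps = 1e-15) {
  stopifnot(inherits(train, "ntcp_cohort"), inherits(test, "ntcp_cohort"))
  if (length(intersect(train$patients$patient_id, test$patients$patient_id)))
    stop("train and test cohorts share patient ids")
  if (is.null(starts)) {
    if (n_starts < 1L) stop("n_starts must be >= 1")
    starts <- with_seed(seed, cbind(
      n = stats::runif(n_starts, bounds$n[1L], bounds$n[2L]),
      m = stats::runif(n_starts, bounds$m[1L], bounds$m[2L]),
      d50 = stats::runif(n_starts, bounds$d50[1L], bounds$d50[2L])
    ))
  } else {
    starts <- as.matrix(starts)
    colnames(starts) <- c("n", "m", "d50")
    n_starts <- nrow(starts)
  }
  y_test <- test$patients$toxicity

  one_fit <- function(i) {
    st <- lkb_params(starts[i, "n"], starts[i, "m"], max(starts[i, "d50"], bounds$d50[1L]))
    fit <- tryCatch(
      lkb_fit(train, method = "gradient_descent", initial = st,
              bounds = bounds, seed = seed,
              control = list(maxit_local = 100L)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      loss <- if (is.null(fit)) NA_real_ else fit$loss
      return(c(converged = 0, loss = loss, test_auc = NA_real_))
    }
    g <- cohort_gmd(test, fit$params$n)
    m_eff <- max(fit$params$m, 1e-6)
    p <- stats::pnorm((g - fit$params$d50) / (m_eff * fit$params$d50))
    p <- pmin(pmax(p, eps), 1 - eps)  # the model's predictions, as fitted
    auc <- tryCatch(roc_auc(p, y_test), error = function(e) NA_real_)
    c(converged = 1, loss = fit$loss, test_auc = auc)
  }

  # budget check from a pilot of up to 5 fits
  pilot_n <- min(5L, n_starts)
  t0 <- proc.time()[["elapsed"]]
  pilot <- t(vapply(seq_len(pilot_n), one_fit, numeric(3)))
  per_fit <- (proc.time()[["elapsed"]] - t0) / pilot_n
  projected <- per_fit * n_starts
  if (projected > budget_s && !force)
    stop(sprintf(
      "projected sweep runtime %.0f s exceeds the %.0f s budget (%d starts at %.2f s each); pass force = TRUE to override",
      projected, budget_s, n_starts, per_fit))

  rest <- if (n_starts > pilot_n)
    t(vapply((pilot_n + 1L):n_starts, one_fit, numeric(3)))
  else NULL
  res <- rbind(pilot, rest)

  conv <- res[, "converged"] == 1
  auc <- res[, "test_auc"]
  classification <- ifelse(!conv, "failed",
                    ifelse(is.na(auc) | auc < predictive_threshold,
                           "nonpredictive", "predictive"))
  records <- data.frame(
    start_n = starts[, "n"], start_m = starts[, "m"],
    start_d50 = starts[, "d50"],
    converged = conv, loss = res[, "loss"], test_auc = auc,
    classification = classification, stringsAsFactors = FALSE
  )
  conv_auc <- auc[conv & !is.na(auc)]
  structure(list(
    n_starts = n_starts,
    frac_failed = mean(classification == "failed"),
    frac_nonpredictive = mean(classification == "nonpredictive"),
    frac_predictive = mean(classification == "predictive"),
    best_loss = suppressWarnings(min(res[, "loss"], na.rm = TRUE)),
    auc_distribution = if (length(conv_auc))
      c(min = min(conv_auc), median = stats::median(conv_auc),
        max = max(conv_auc))
    else c(min = NA_real_, median = NA_real_, max = NA_real_),
    predictive_threshold = predictive_threshold,
    seed = as.integer(seed),
    start_distribution = "uniform over bounds box",
    records = records
  ), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "Convergence sweep: %d starts | failed %.2f%% | non-predictive %.2f%% | predictive %.2f%%\n",
    x$n_starts, 100 * x$frac_failed, 100 * x$frac_nonpredictive,
    100 * x$frac_predictive))
  cat(sprintf("best loss %.6f nats | converged-fit test AUC min/median/max = %.3f/%.3f/%.3f\n",
              x$best_loss, x$auc_distribution["min"],
              x$auc_distribution["median"], x$auc_distribution["max"]))
  invisible(x)
}

#' Write sweep outputs (per-start CSV + summary JSON)
#'
#' @param sw A [run_sweep()] result.
#' @param path_csv Per-start records CSV path (or `NULL`).
#' @param path_json Summary JSON path (or `NULL`).
#' @return Invisibly, `sw`.
#' @export
write_sweep <- function(sw, path_csv = NULL, path_json = NULL) {
  stopifnot(inherits(sw, "sweep_result"))
  if (!is.null(path_csv))
    utils::write.csv(sw$records, path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    x <- unclass(sw)
    x$records <- NULL
    x$auc_distribution <- as.list(x$auc_distribution)
    jsonlite::write_json(x, path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(sw)
}
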