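# Parametric empirical-Bayes ComBat harmonization of scalar per-patient
# features across centres (batches). Scalar features only: a DVH curve is
# not a valid input here -- the dose-volume histogram feeds the LKB model
# uncorrected, which is exactly the asymmetry between the two modelling arms.

aprior <- function(delta_hat) {
  m <- mean(delta_hat); s2 <- stats::var(delta_hat)
  (2 * s2 + m^2) / s2
}
bprior <- function(delta_hat) {
  m <- mean(delta_hat); s2 <- stats::var(delta_hat)
  (m * s2 + m^3) / s2
}
postmean <- function(g_hat, g_bar, n, d_star, t2) {
  (t2 * n * g_hat + d_star * g_bar) / (t2 * n + d_star)
}
postvar <- function(sum2, n, a, b) {
  (0.5 * sum2 + b) / (n / 2 + a - 1)
}

# EB iteration for one batch: sdat is samples x features (standardized).
eb_iterate <- function(sdat, g_hat, d_hat, g_bar, t2, a, b, conv = 1e-4) {
  n <- nrow(sdat)
  g_old <- g_hat
  d_old <- d_hat
  change <- 1
  count <- 0L
  while (change > conv) {
    g_new <- postmean(g_hat, g_bar, n, d_old, t2)
    sum2 <- colSums((sdat - matrix(g_new, n, length(g_new), byrow = TRUE))^2)
    d_new <- postvar(sum2, n, a, b)
    change <- max(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
    g_old <- g_new
    d_old <- d_new
    count <- count + 1L
    if (count > 10000L) break
  }
  list(gamma_star = g_old, delta_star = d_old, iterations = count)
}

as_feature_matrix <- function(features) {
  x <- as.matrix(features)
  if (!is.numeric(x)) stop("features must be numeric")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

#' Fit a ComBat harmonization model
#'
#' Estimates the parametric empirical-Bayes ComBat model on a
#' patients-by-features table of scalar measurements with a batch (centre)
#' label per patient. Each feature is standardized by the batch-size-weighted
#' grand mean and the pooled residual variance; per-batch additive effects
#' get a normal prior and multiplicative effects an inverse-gamma prior, with
#' hyperparameters estimated across features by moment matching; the
#' conditional posterior means are iterated to convergence (relative change
#' `< 1e-4`).
#'
#' With a single feature the EB hyperpriors cannot be estimated (they pool
#' across features), so the unshrunk per-batch location/scale estimates are
#' used directly; this is noted in the returned model.
#'
#' @param features Patients-by-features numeric table (matrix or data
#'   frame); no missing values.
#' @param batch Batch (centre) identifier per patient; at least 2 batches,
#'   each with at least 3 patients.
#' @return An object of class `combat_model`: per-feature grand mean and
#'   pooled variance, per (batch, feature) additive (`gamma_star`) and
#'   multiplicative (`delta_star > 0`) effects, batch sizes and ids.
#' @examples
#' x <- cbind(dose = c(rnorm(5, 30), rnorm(5, 40)), age = rnorm(10, 60))
#' m <- combat_fit(x, rep(c("a", "b"), each = 5))
#' corrected <- combat_apply(m, x, rep(c("a", "b"), each = 5))
#' @export
combat_fit <- function(features, batch) {
  x <- as_feature_matrix(features)
  batch <- as.character(batch)
  if (length(batch) != nrow(x))
    stop("need one batch id per patient (row)")
  if (anyNA(x)) stop("features must not contain missing values")
  ids <- sort(unique(batch))
  if (length(ids) < 2L)
    stop("only one batch present: nothing to correct")
  sizes <- table(factor(batch, levels = ids))
  if (any(sizes < 3L))
    stop(sprintf("every batch needs >= 3 patients (smallest has %d)", min(sizes)))
  for (b in ids) for (f in colnames(x)) {
    v <- stats::var(x[batch == b, f])
    if (!is.finite(v) || v == 0)
      stop(sprintf("feature '%s' has zero variance within batch '%s'", f, b))
  }
  n_total <- nrow(x)
  nf <- ncol(x)

  # per-batch means, weighted grand mean, pooled residual variance (/ n)
  batch_means <- do.call(rbind, lapply(ids, function(b)
    colMeans(x[batch == b, , drop = FALSE])))
  rownames(batch_means) <- ids
  w <- as.numeric(sizes) / n_total
  grand_mean <- drop(w %*% batch_means)
  fitted <- batch_means[batch, , drop = FALSE]
  var_pooled <- colSums((x - fitted)^2) / n_total

  z <- sweep(sweep(x, 2L, grand_mean, "-"), 2L, sqrt(var_pooled), "/")

  gamma_hat <- do.call(rbind, lapply(ids, function(b)
    colMeans(z[batch == b, , drop = FALSE])))
  delta_hat <- do.call(rbind, lapply(ids, function(b)
    apply(z[batch == b, , drop = FALSE], 2L, stats::var)))
  rownames(gamma_hat) <- rownames(delta_hat) <- ids

  shrunk <- nf >= 2L
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  if (shrunk) {
    for (b in ids) {
      g_bar <- mean(gamma_hat[b, ])
      t2 <- stats::var(gamma_hat[b, ])
      a <- aprior(delta_hat[b, ])
      bp <- bprior(delta_hat[b, ])
      sol <- eb_iterate(z[batch == b, , drop = FALSE],
                        gamma_hat[b, ], delta_hat[b, ], g_bar, t2, a, bp)
      gamma_star[b, ] <- sol$gamma_star
      delta_star[b, ] <- sol$delta_star
    }
  }
  structure(list(
    batches = ids,
    batch_sizes = as.integer(sizes),
    features = colnames(x),
    grand_mean = grand_mean,
    var_pooled = var_pooled,
    gamma_star = gamma_star,
    delta_star = delta_star,
    eb_shrunk = shrunk
  ), class = "combat_model")
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("ComBat model: %d batches (%s), %d feature(s)%s\n",
              length(x$batches), paste(x$batches, collapse = ", "),
              length(x$features),
              if (x$eb_shrunk) ", EB-shrunk" else ", unshrunk (single feature)"))
  invisible(x)
}

#' Apply a fitted ComBat model
#'
#' Harmonizes a feature table: each value is standardized with the model's
#' grand mean and pooled variance, the batch's additive effect is removed
#' and its multiplicative effect divided out, and the result is returned to
#' the original scale:
#' \deqn{x^* = \frac{\sigma_{pooled}}{\sqrt{\delta^*_b}}\,(z - \gamma^*_b)
#'   + \bar{x}.}
#' Deterministic; batches unseen at fit time are refused (there is no
#' reference-batch fallback).
#'
#' @param model A [combat_fit()] result.
#' @param features Patients-by-features table with the model's feature set.
#' @param batch Batch id per patient; all must be known to the model.
#' @return Corrected feature matrix, same shape and column names.
#' @export
combat_apply <- function(model, features, batch) {
  stopifnot(inherits(model, "combat_model"))
  x <- as_feature_matrix(features)
  batch <- as.character(batch)
  if (length(batch) != nrow(x))
    stop("need one batch id per patient (row)")
  if (!setequal(colnames(x), model$features))
    stop("feature columns do not match the fitted model")
  x <- x[, model$features, drop = FALSE]
  unseen <- setdiff(unique(batch), model$batches)
  if (length(unseen))
    stop(sprintf("batch id(s) not seen at fit time: %s",
                 paste(unseen, collapse = ", ")))
  z <- sweep(sweep(x, 2L, model$grand_mean, "-"), 2L,
             sqrt(model$var_pooled), "/")
  out <- z
  for (b in model$batches) {
    rows <- batch == b
    if (!any(rows)) next
    zb <- z[rows, , drop = FALSE]
    zb <- sweep(zb, 2L, model$gamma_star[b, ], "-")
    zb <- sweep(zb, 2L, sqrt(model$delta_star[b, ]), "/")
    out[rows, ] <- zb
  }
  out <- sweep(sweep(out, 2L, sqrt(model$var_pooled), "*"), 2L,
               model$grand_mean, "+")
  out
}

#' Serialize a ComBat model to JSON
#'
#' @param model A `combat_model` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_combat_json <- function(model, path) {
  stopifnot(inherits(model, "combat_model"))
  x <- unclass(model)
  x$gamma_star <- as.data.frame(x$gamma_star)
  x$delta_star <- as.data.frame(x$delta_star)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
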