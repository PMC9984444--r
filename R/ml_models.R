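# Classifier backends for the benchmark arm. Each backend exposes
# fit(x, y, hyper, seed) -> handle and predict(handle, x) -> probability of
# the positive class. x is always a plain numeric matrix (one-hot encoded
# upstream), y a 0/1 vector.
#
# LR is ridge-penalized logistic regression (glmnet, binomial); its "C"
# hyperparameter is the inverse regularization strength, lambda = 1/(C * N).
# DT is a CART tree split on Gini impurity (rpart). GB is gradient-boosted
# trees on the logistic loss (xgboost). AB is discrete AdaBoost (SAMME) over
# depth-limited CART trees, written here; probabilities come from the
# logistic of twice the normalized weighted-vote margin, the usual
# decision-function convention.

ml_model_ids <- c("AB", "LR", "DT", "GB")

fit_lr <- function(x, y, hyper, seed) {
  C <- hyper$C %||% 1
  if (ncol(x) < 2L) x <- cbind(x, .pad = 0)
  lambda <- 1 / (C * nrow(x))
  fit <- glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                        alpha = 0, lambda = lambda, standardize = TRUE)
  list(fit = fit, lambda = lambda, pad = ncol(x) > 0)
}
predict_lr <- function(h, x) {
  if (ncol(x) < 2L) x <- cbind(x, .pad = 0)
  as.numeric(stats::predict(h$fit, newx = x, type = "response", s = h$lambda))
}

fit_dt <- function(x, y, hyper, seed) {
  df <- data.frame(y = factor(y, levels = c(0, 1)), x, check.names = FALSE)
  rpart::rpart(
    y ~ ., data = df, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(
      maxdepth = hyper$max_depth %||% 4,
      minbucket = hyper$min_leaf %||% 5,
      cp = 0, xval = 0
    )
  )
}
predict_dt <- function(h, x) {
  df <- as.data.frame(x, check.names = FALSE)
  as.numeric(stats::predict(h, newdata = df, type = "prob")[, "1"])
}

fit_gb <- function(x, y, hyper, seed) {
  xgboost::xgb.train(
    params = list(
      objective = "binary:logistic",
      eta = hyper$learning_rate %||% 0.1,
      max_depth = hyper$max_depth %||% 3,
      nthread = 1,
      seed = as.integer(seed)
    ),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
    nrounds = hyper$n_estimators %||% 100,
    verbose = 0
  )
}
predict_gb <- function(h, x)
  as.numeric(stats::predict(h, xgboost::xgb.DMatrix(x, nthread = 1)))

fit_ab <- function(x, y, hyper, seed) {
  n_est <- hyper$n_estimators %||% 100
  lr <- hyper$learning_rate %||% 0.5
  depth <- hyper$max_depth %||% 1
  n <- nrow(x)
  df <- data.frame(y = factor(y, levels = c(0, 1)), x, check.names = FALSE)
  w <- rep(1 / n, n)
  stumps <- vector("list", n_est)
  alphas <- numeric(n_est)
  used <- 0L
  ctl <- rpart::rpart.control(maxdepth = depth, cp = 0, xval = 0,
                              minbucket = max(1, floor(n / 50)))
  for (t in seq_len(n_est)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                        parms = list(split = "gini"), control = ctl)
    pred <- as.integer(stats::predict(fit, df, type = "class")) - 1L
    miss <- pred != y
    err <- sum(w[miss])
    if (err >= 0.5) break  # weak learner no better than chance
    err <- max(err, 1e-10)
    alpha <- lr * 0.5 * log((1 - err) / err)
    w <- w * exp(ifelse(miss, alpha, -alpha))
    w <- w / sum(w)
    used <- used + 1L
    stumps[[used]] <- fit
    alphas[used] <- alpha
    if (err <= 1e-10) break  # perfect weak learner; further rounds degenerate
  }
  if (used == 0L) {
    # no usable weak learner: fall back to the prevalence predictor
    return(list(stumps = list(), alphas = numeric(0), prior = mean(y)))
  }
  list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)],
       prior = mean(y))
}
predict_ab <- function(h, x) {
  if (length(h$stumps) == 0L) return(rep(h$prior, nrow(x)))
  df <- as.data.frame(x, check.names = FALSE)
  score <- numeric(nrow(x))
  for (t in seq_along(h$stumps)) {
    pred <- as.integer(stats::predict(h$stumps[[t]], df, type = "class")) - 1L
    score <- score + h$alphas[t] * (2 * pred - 1)
  }
  margin <- score / sum(h$alphas)
  stats::plogis(2 * margin)
}

ml_backend <- function(model_id) {
  switch(model_id,
    AB = list(fit = fit_ab, predict = predict_ab),
    LR = list(fit = fit_lr, predict = predict_lr),
    DT = list(fit = fit_dt, predict = predict_dt),
    GB = list(fit = fit_gb, predict = predict_gb),
    stop(sprintf("unknown model id '%s' (expected one of %s)", model_id,
                 paste(ml_model_ids, collapse = ", ")))
  )
}

#' Default hyperparameter grid for a classifier
#'
#' Conventional search ranges: AdaBoost over ensemble size and learning
#' rate; ridge logistic regression over six log-spaced inverse
#' regularization strengths; decision tree over depth and minimum leaf
#' size; gradient boosting over ensemble size, learning rate and depth.
#' All grids are overridable in [model_spec()].
#'
#' @param model_id One of `"AB"`, `"LR"`, `"DT"`, `"GB"`.
#' @return Named list mapping hyperparameter name to candidate values.
#' @export
default_grid <- function(model_id) {
  switch(model_id,
    AB = list(n_estimators = c(50, 200, 400), learning_rate = c(0.01, 0.1, 1)),
    LR = list(C = 10^seq(-3, 2, length.out = 6)),
    DT = list(max_depth = c(1, 2, 4, 8), min_leaf = c(1, 5, 20)),
    GB = list(n_estimators = c(50, 200, 400), learning_rate = c(0.01, 0.1, 0.3),
              max_depth = c(1, 2, 4)),
    stop(sprintf("unknown model id '%s'", model_id))
  )
}
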