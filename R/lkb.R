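#' LKB model parameters
#'
#' The parameter triple of the Lyman-Kutcher-Burman NTCP model: `n`, the
#' tissue dose-volume dependence (seriality) entering the generalized mean
#' dose; `m`, the slope of the probit dose-response; and `D50`, the dose in
#' Gy giving a 50% complication probability.
#'
#' @param n Dose-volume dependence, unitless, positive.
#' @param m Slope parameter, unitless, in `[0, 1]`.
#' @param d50 Dose at 50% complication probability, Gy, positive.
#' @return An object of class `lkb_params`.
#' @examples
#' lkb_params(n = 1, m = 0.55, d50 = 47)
#' @export
lkb_params <- function(n, m, d50) {
  stopifnot(is.numeric(n), is.numeric(m), is.numeric(d50),
            length(n) == 1L, length(m) == 1L, length(d50) == 1L)
  if (!is.finite(n) || n <= 0) stop("n must be positive and finite")
  if (!is.finite(m) || m < 0 || m > 1) stop("m must lie in [0, 1]")
  if (!is.finite(d50) || d50 <= 0) stop("d50 must be positive and finite")
  structure(list(n = n, m = m, d50 = d50), class = "lkb_params")
}

#' @export
print.lkb_params <- function(x, ...) {
  cat(sprintf("LKB parameters: n = %.4g, m = %.4g, D50 = %.4g Gy\n",
              x$n, x$m, x$d50))
  invisible(x)
}

#' Default LKB fitting bounds
#'
#' The parameter box used by the fitter and the convergence sweep:
#' `n` in `[0.01, 4]`, `m` in `[0, 1]`, `D50` in `(0, 120]` Gy. The lower
#' `n` bound matters: fitting with bounds that admit very small `n` fails
#' numerically, because the generalized mean dose raises doses to the power
#' `1/n`. The open lower endpoint on `D50` is realized as 0.01 Gy. 120 Gy
#' safely exceeds clinical head-and-neck prescription doses.
#'
#' @param n_max Upper bound on `n` (default 4).
#' @param d50_max Upper bound on `D50` in Gy (default 120).
#' @return A named list of length-2 numeric ranges for `n`, `m`, `d50`.
#' @export
lkb_bounds <- function(n_max = 4, d50_max = 120) {
  list(n = c(0.01, n_max), m = c(0, 1), d50 = c(0.01, d50_max))
}

#' LKB normal tissue complication probability
#'
#' Evaluates the LKB probit dose-response
#' \deqn{\mathrm{NTCP} = \tfrac{1}{2}\Big[1 + \mathrm{erf}\Big(
#'   \frac{\mathrm{GMD} - D_{50}}{\sqrt{2}\, m\, D_{50}}\Big)\Big]
#'   = \Phi\!\Big(\frac{\mathrm{GMD} - D_{50}}{m\, D_{50}}\Big),}
#' the standard normal CDF of the scaled dose excess over `D50`. At
#' `GMD = D50` the probability is exactly one half for any `m` and `D50`.
#'
#' @param gmd Generalized mean dose in Gy (vectorized), non-negative.
#' @param params An [lkb_params] object with `m >= m_floor`.
#' @param m_floor Evaluation floor on `m` (default `1e-6`); below it the
#'   dose-response degenerates to a step function and evaluation is refused.
#' @return Complication probabilities in `(0, 1)`, strictly increasing in
#'   `gmd`.
#' @examples
#' ntcp(47, lkb_params(1, 0.55, 47))  # exactly 0.5
#' @export
ntcp <- function(gmd, params, m_floor = 1e-6) {
  stopifnot(inherits(params, "lkb_params"))
  if (any(!is.finite(gmd)) || any(gmd < 0))
    stop("gmd must be finite and non-negative")
  if (params$m < m_floor)
    stop(sprintf("m = %g is below the evaluation floor %g (step-function degeneracy)",
                 params$m, m_floor))
  stats::pnorm((gmd - params$d50) / (params$m * params$d50))
}

#' Mean log-loss of an LKB model over a cohort
#'
#' The mean binomial negative log-likelihood (cross-entropy, nats) of the
#' observed binary toxicity labels under NTCP probabilities computed from
#' each patient's generalized mean dose at the model's `n`:
#' \deqn{-\frac{1}{N}\sum_i \big[y_i \log p_i + (1-y_i)\log(1-p_i)\big].}
#' Probabilities are clipped to `[eps, 1-eps]` so the loss stays finite over
#' the whole fitting box, including the `m -> 0` limit (for which `m` is
#' floored at `1e-6` internally rather than refused, so that optimizers may
#' legally visit the `m = 0` bound).
#'
#' @param ch An [cohort()] object.
#' @param params An [lkb_params] object.
#' @param eps Probability clipping constant (default `1e-15`).
#' @return Mean log-loss in nats (non-negative, finite).
#' @export
cohort_log_loss <- function(ch, params, eps = 1e-15) {
  stopifnot(inherits(ch, "ntcp_cohort"), inherits(params, "lkb_params"))
  y <- ch$patients$toxicity
  g <- cohort_gmd(ch, params$n)
  m_eff <- max(params$m, 1e-6)
  p <- stats::pnorm((g - params$d50) / (m_eff * params$d50))
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

lkb_param_names <- c("n", "m", "d50")

# flatten bounds list into lower/upper vectors for a set of free parameters
bounds_box <- function(bounds, free) {
  lower <- vapply(bounds[free], `[`, numeric(1), 1L)
  upper <- vapply(bounds[free], `[`, numeric(1), 2L)
  list(lower = lower, upper = upper)
}

#' Fit the LKB model to a cohort by log-loss minimization
#'
#' Minimizes [cohort_log_loss()] over the parameter box. Three optimizers
#' are available:
#' \describe{
#'   \item{`gradient_descent`}{bounded local quasi-Newton descent (L-BFGS-B)
#'     with central finite-difference gradients (the loss gradient has no
#'     known analytic form). Requires an initial point. Fast, but on this
#'     non-convex surface it may stall in a poor basin or fail outright
#'     depending on the start.}
#'   \item{`dual_annealing`}{seeded annealing chain with a heavy-tailed
#'     visiting distribution plus local refinement.}
#'   \item{`differential_evolution`}{seeded DE/rand/1/bin population search
#'     (population 15 x dimension) with a final local polish.}
#' }
#'
#' A fit is reported as converged only when the optimizer signals success,
#' the final loss is finite, and every free parameter lies inside the box
#' (up to a `1e-8` tolerance). A boundary value — typically `n` pinned at a
#' bound — can still be a legitimate maximum-likelihood estimate on cohorts
#' where the profile in `n` is monotone, so it does not by itself void
#' convergence; outright optimizer failure does.
#'
#' Bounds admitting `n < 0.01` are refused by default: power-mean evaluation
#' with very small `n` is the classic numerical-infinity hazard of this
#' model. Pass `allow_unsafe_bounds = TRUE` only to study that failure mode
#' deliberately.
#'
#' @param ch An [cohort()] object.
#' @param method One of `"dual_annealing"`, `"differential_evolution"`,
#'   `"gradient_descent"`.
#' @param initial Optional [lkb_params] starting point (required for
#'   `gradient_descent`); must lie inside `bounds`.
#' @param bounds Parameter box as produced by [lkb_bounds()].
#' @param fixed Optional named list pinning parameters, e.g.
#'   `list(n = 1)` for the two-parameter mean-dose model.
#' @param seed Integer seed driving the global optimizers.
#' @param control Optional list of optimizer settings: `maxiter`
#'   (annealing iterations / DE generations, default 1000), `maxit_local`
#'   (local iteration cap, default 200).
#' @param allow_unsafe_bounds Permit `n` bounds below 0.01 (see above).
#' @return An object of class `lkb_fit`: fitted [lkb_params], final mean
#'   log-loss (`loss`, nats), `converged` flag, `optimizer`,
#'   `n_evaluations`, `elapsed` seconds, `df` (number of free parameters),
#'   `seed`, `bounds` and `fixed`.
#' @examples
#' \donttest{
#' sim <- simulate_cohorts(sim_config(n_train = 120, n_test = 40, seed = 7))
#' fit <- lkb_fit(sim$train, method = "differential_evolution",
#'                control = list(maxiter = 60), seed = 1)
#' fit$params
#' }
#' @export
lkb_fit <- function(ch,
                    method = c("dual_annealing", "differential_evolution",
                               "gradient_descent"),
                    initial = NULL,
                    bounds = lkb_bounds(),
                    fixed = NULL,
                    seed = 1L,
                    control = list(),
                    allow_unsafe_bounds = FALSE) {
  stopifnot(inherits(ch, "ntcp_cohort"))
  method <- match.arg(method)
  if (!all(lkb_param_names %in% names(bounds)))
    stop("bounds must name n, m and d50")
  if (bounds$n[1L] < 0.01 && !allow_unsafe_bounds)
    stop(paste("bounds admit n < 0.01: small n risks computational infinities",
               "in the generalized-mean-dose evaluation; set",
               "allow_unsafe_bounds = TRUE to override"))
  if (!is.null(fixed)) {
    if (!all(names(fixed) %in% lkb_param_names))
      stop("fixed may only name n, m, d50")
    if (length(fixed) >= 3L) stop("at least one parameter must remain free")
  }
  free <- setdiff(lkb_param_names, names(fixed))
  box <- bounds_box(bounds, free)

  full_par <- function(theta) {
    p <- as.list(theta)
    names(p) <- free
    for (nm in names(fixed)) p[[nm]] <- fixed[[nm]]
    p
  }
  objective <- function(theta) {
    p <- full_par(theta)
    cohort_log_loss(ch, lkb_params(max(p$n, 1e-12), min(max(p$m, 0), 1),
                                   max(p$d50, 1e-12)))
  }

  t0 <- proc.time()[["elapsed"]]
  maxiter <- control$maxiter %||% 1000L
  maxit_local <- control$maxit_local %||% 200L

  if (method == "gradient_descent") {
    if (is.null(initial))
      stop("gradient_descent requires an initial point")
    stopifnot(inherits(initial, "lkb_params"))
    th0 <- vapply(free, function(nm) initial[[nm]], numeric(1))
    if (any(th0 < box$lower) || any(th0 > box$upper))
      stop("initial point lies outside bounds")
    res <- optimize_local(objective, th0, box$lower, box$upper,
                          maxit = maxit_local)
  } else if (method == "dual_annealing") {
    res <- optimize_anneal(objective, box$lower, box$upper, seed = seed,
                           maxiter = maxiter)
  } else {
    res <- optimize_de(objective, box$lower, box$upper, seed = seed,
                       maxiter = maxiter)
  }
  elapsed <- proc.time()[["elapsed"]] - t0

  interior <- all(res$par >= box$lower - 1e-8) &&
    all(res$par <= box$upper + 1e-8)
  pl <- full_par(res$par)
  params <- lkb_params(pl$n, max(pl$m, 0), pl$d50)
  structure(list(
    params = params,
    loss = res$value,
    converged = isTRUE(res$success) && is.finite(res$value) && interior,
    optimizer = method,
    n_evaluations = res$n_evaluations,
    elapsed = elapsed,
    df = length(free),
    seed = as.integer(seed),
    bounds = bounds,
    fixed = fixed,
    message = res$message
  ), class = "lkb_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lkb_fit <- function(x, ...) {
  cat(sprintf("LKB fit (%s): %s\n", x$optimizer,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  cat(sprintf("mean log-loss %.6f nats | %d free parameter(s) | %d evaluations | %.2f s\n",
              x$loss, x$df, x$n_evaluations, x$elapsed))
  invisible(x)
}

#' Serialize an LKB fit to JSON
#'
#' @param fit An `lkb_fit` object.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "lkb_fit"))
  x <- list(
    params = unclass(fit$params),
    loss = fit$loss,
    converged = fit$converged,
    optimizer = fit$optimizer,
    n_evaluations = fit$n_evaluations,
    elapsed = fit$elapsed,
    df = fit$df,
    seed = fit$seed,
    bounds = fit$bounds,
    fixed = fit$fixed
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Loss and gradient over an (n, D50) grid
#'
#' Evaluates the cohort log-loss and its central-difference gradient on a
#' rectangular grid in `(n, D50)` at fixed `m` — the landscape view that
#' exposes why local descent can be led in opposite directions from nearby
#' starting points.
#'
#' @param ch An [cohort()] object.
#' @param n_grid Strictly positive grid of `n` values, within `bounds$n`.
#' @param d50_grid Grid of `D50` values (Gy), within `bounds$d50`.
#' @param m_fixed Fixed slope in `(0, 1]`.
#' @param bounds Parameter box (default [lkb_bounds()]).
#' @param h_rel Relative step for the central differences (default `1e-4`).
#' @return A data frame with one row per grid node and columns `n`, `d50`,
#'   `loss`, `grad_n`, `grad_d50`, suitable for quiver/heatmap rendering.
#' @export
loss_landscape <- function(ch, n_grid, d50_grid, m_fixed,
                           bounds = lkb_bounds(), h_rel = 1e-4) {
  stopifnot(inherits(ch, "ntcp_cohort"),
            length(n_grid) >= 1L, length(d50_grid) >= 1L)
  if (!(m_fixed > 0 && m_fixed <= 1))
    stop("m_fixed must lie in (0, 1]")
  bad_n <- n_grid[n_grid < bounds$n[1L] | n_grid > bounds$n[2L]]
  bad_d <- d50_grid[d50_grid < bounds$d50[1L] | d50_grid > bounds$d50[2L]]
  if (length(bad_n) || length(bad_d))
    stop(sprintf("grid nodes out of bounds: n = {%s}, d50 = {%s}",
                 paste(bad_n, collapse = ", "), paste(bad_d, collapse = ", ")))
  f <- function(n, d50) cohort_log_loss(ch, lkb_params(n, m_fixed, d50))
  grid <- expand.grid(n = n_grid, d50 = d50_grid, KEEP.OUT.ATTRS = FALSE)
  res <- t(mapply(function(n, d50) {
    hn <- h_rel * max(1, n)
    hd <- h_rel * max(1, d50)
    c(loss = f(n, d50),
      grad_n = (f(n + hn, d50) - f(n - hn, d50)) / (2 * hn),
      grad_d50 = (f(n, d50 + hd) - f(n, d50 - hd)) / (2 * hd))
  }, grid$n, grid$d50))
  cbind(grid, as.data.frame(res))
}
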