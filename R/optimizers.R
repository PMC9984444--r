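# Bound-constrained optimizers used by the LKB fitter.
#
# All three share a small contract: minimize fn over a box, return
# list(par, value, success, n_evaluations, message). The two global methods
# are seeded and fully reproducible per seed. They are implemented here
# because the model's log-loss surface is non-convex with basin structure,
# so a single local descent is not trustworthy.

# Evaluate fn while counting calls; non-finite values are mapped to a large
# finite penalty so annealing/DE chains never stall on an invalid point.
make_counted_fn <- function(fn, penalty = 1e10) {
  count <- 0L
  list(
    f = function(x) {
      count <<- count + 1L
      v <- tryCatch(fn(x), error = function(e) NaN)
      if (!is.finite(v)) penalty else v
    },
    calls = function() count
  )
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Central finite-difference gradient, relative step h (the loss gradient has
# no known analytic form, so every gradient here is numerical).
numeric_gradient <- function(f, x, h_rel = 1e-6) {
  d <- length(x)
  g <- numeric(d)
  for (j in seq_len(d)) {
    h <- h_rel * max(1, abs(x[j]))
    xp <- x; xm <- x
    xp[j] <- x[j] + h
    xm[j] <- x[j] - h
    g[j] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# Local bounded quasi-Newton descent (L-BFGS-B) with central-difference
# gradients. The "gradient descent" arm of the study.
optimize_local <- function(fn, init, lower, upper, maxit = 200L, h_rel = 1e-6) {
  cf <- make_counted_fn(fn)
  # keep finite-difference probes inside the box
  fgrad <- function(x) {
    xc <- pmin(pmax(x, lower), upper)
    g <- numeric(length(x))
    for (j in seq_along(x)) {
      h <- h_rel * max(1, abs(xc[j]))
      h <- min(h, (upper[j] - lower[j]) / 4)
      xp <- xc; xm <- xc
      xp[j] <- min(xc[j] + h, upper[j])
      xm[j] <- max(xc[j] - h, lower[j])
      dh <- xp[j] - xm[j]
      g[j] <- if (dh > 0) (cf$f(xp) - cf$f(xm)) / dh else 0
    }
    g
  }
  res <- tryCatch(
    stats::optim(init, cf$f, gr = fgrad, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = maxit)),
    error = function(e) list(par = init, value = NaN, convergence = 99L,
                             message = conditionMessage(e))
  )
  list(par = res$par, value = res$value,
       success = identical(res$convergence, 0L) && is.finite(res$value),
       n_evaluations = cf$calls(),
       message = if (is.null(res$message)) "" else res$message)
}

# Differential evolution, classic DE/rand/1/bin with dithered F and binomial
# crossover; population 15 x dim; early stop when the population's fitness
# spread collapses; best member polished by the local method.
optimize_de <- function(fn, lower, upper, seed, maxiter = 1000L,
                        pop_mult = 15L, cr = 0.9, tol = 1e-8,
                        polish = TRUE) {
  d <- length(lower)
  np <- pop_mult * d
  cf <- make_counted_fn(fn)
  out <- with_seed(seed, {
    pop <- matrix(stats::runif(np * d, rep(lower, each = np), rep(upper, each = np)),
                  nrow = np, ncol = d)
    fit <- apply(pop, 1L, cf$f)
    for (gen in seq_len(maxiter)) {
      Fd <- stats::runif(1, 0.5, 1.0)  # dither per generation
      for (i in seq_len(np)) {
        idx <- sample.int(np, 3L)
        while (any(idx == i)) idx <- sample.int(np, 3L)
        mut <- pop[idx[1L], ] + Fd * (pop[idx[2L], ] - pop[idx[3L], ])
        mut <- pmin(pmax(mut, lower), upper)
        cross <- stats::runif(d) < cr
        cross[sample.int(d, 1L)] <- TRUE
        trial <- ifelse(cross, mut, pop[i, ])
        ft <- cf$f(trial)
        if (ft <= fit[i]) {
          pop[i, ] <- trial
          fit[i] <- ft
        }
      }
      if (max(fit) - min(fit) < tol * (abs(min(fit)) + tol)) break
    }
    b <- which.min(fit)
    list(par = pop[b, ], value = fit[b])
  })
  success <- is.finite(out$value)
  if (polish) {
    pol <- optimize_local(fn, out$par, lower, upper)
    if (is.finite(pol$value) && pol$value <= out$value) {
      out$par <- pol$par
      out$value <- pol$value
    }
    success <- success && (pol$success || is.finite(out$value))
  }
  list(par = out$par, value = out$value, success = success,
       n_evaluations = cf$calls(), message = "")
}

# Annealing-based global search: a generalized simulated-annealing chain with
# a heavy-tailed (Cauchy) visiting distribution whose scale shrinks with the
# temperature, Metropolis acceptance, and local quasi-Newton refinement of
# each new incumbent -- the global-plus-local pairing of the dual-annealing
# family.
optimize_anneal <- function(fn, lower, upper, seed, maxiter = 1000L,
                            t0 = 5230, qv = 2.62, polish = TRUE) {
  d <- length(lower)
  width <- upper - lower
  cf <- make_counted_fn(fn)
  out <- with_seed(seed, {
    x <- stats::runif(d, lower, upper)
    fx <- cf$f(x)
    best <- x; fbest <- fx
    tfact <- (2^(qv - 1) - 1)
    for (t in seq_len(maxiter)) {
      Tt <- t0 * tfact / ((1 + t)^(qv - 1) - 1)
      scale <- min(1, Tt / t0)
      for (k in seq_len(2L * d)) {
        step <- scale * width * stats::rcauchy(d) * 0.1
        xp <- x + step
        # fold proposals back into the box
        xp <- lower + abs((xp - lower) %% (2 * width))
        xp <- ifelse(xp > upper, 2 * upper - xp, xp)
        xp <- pmin(pmax(xp, lower), upper)
        fp <- cf$f(xp)
        if (fp <= fx || stats::runif(1) < exp(-(fp - fx) / max(Tt * 1e-4, 1e-12))) {
          x <- xp; fx <- fp
        }
        if (fx < fbest) { best <- x; fbest <- fx }
      }
      # periodic local refinement of the incumbent
      if (t %% 100L == 0L) {
        pol <- optimize_local(function(z) cf$f(z), best, lower, upper, maxit = 100L)
        if (is.finite(pol$value) && pol$value < fbest) {
          best <- pol$par; fbest <- pol$value
          x <- best; fx <- fbest
        }
      }
    }
    list(par = best, value = fbest)
  })
  success <- is.finite(out$value)
  if (polish) {
    pol <- optimize_local(fn, out$par, lower, upper)
    if (is.finite(pol$value) && pol$value <= out$value) {
      out$par <- pol$par
      out$value <- pol$value
    }
    success <- success && is.finite(out$value)
  }
  list(par = out$par, value = out$value, success = success,
       n_evaluations = cf$calls(), message = "")
}
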