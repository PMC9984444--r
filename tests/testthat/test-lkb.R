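test_that("ntcp returns one half at D50 and matches an erf oracle elsewhere", {
  for (m in c(0.1, 0.55, 1)) for (d50 in c(30, 47, 60))
    expect_equal(ntcp(d50, lkb_params(1, m, d50)), 0.5, tolerance = 1e-12)

  # independent oracle: the probit written out via erf
  skip_if_not_installed("pracma")
  erf_ntcp <- function(g, m, d50)
    0.5 * (1 + pracma::erf((g - d50) / (sqrt(2) * m * d50)))
  # zero dose with m = 0.5: two standard deviations below D50
  expect_equal(ntcp(0, lkb_params(1, 0.5, 40)), erf_ntcp(0, 0.5, 40),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:25) {
    g <- runif(1, 0, 100); m <- runif(1, 0.05, 1); d50 <- runif(1, 20, 100)
    # absolute comparison: relative tolerance is meaningless in deep tails
    expect_lt(abs(ntcp(g, lkb_params(1, m, d50)) - erf_ntcp(g, m, d50)),
              1e-13)
  }
})

test_that("ntcp is monotone in gmd, decreasing in D50, and saturates", {
  p <- lkb_params(1, 0.4, 50)
  g <- seq(0, 200, by = 5)
  v <- ntcp(g, p)
  expect_true(all(diff(v) > 0))
  expect_gt(ntcp(500, p), 1 - 1e-10)
  expect_gt(ntcp(40, lkb_params(1, 0.4, 45)), ntcp(40, lkb_params(1, 0.4, 55)))
})

test_that("ntcp refuses the step-function degeneracy", {
  expect_error(ntcp(40, lkb_params(1, 0, 50)), "floor")
})

test_that("cohort log-loss matches hand computation and the constant-half value", {
  # every p = 0.5: patients at exactly D50
  ch <- toy_cohort(list(a = dvh(47, 1), b = dvh(47, 1)), c(1, 0))
  expect_equal(cohort_log_loss(ch, lkb_params(1, 0.55, 47)), log(2),
               tolerance = 1e-12)

  # 4-patient toy cohort, term-by-term via pnorm
  doses <- c(20, 40, 55, 70)
  y <- c(0, 1, 0, 1)
  ch4 <- toy_cohort(lapply(doses, function(d) dvh(d, 1)), y)
  prm <- lkb_params(1, 0.5, 45)
  p <- pnorm((doses - 45) / (0.5 * 45))
  byhand <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(cohort_log_loss(ch4, prm), byhand, tolerance = 1e-12)

  # perfect confident prediction on a single patient is ~0 loss
  ch1 <- toy_cohort(list(a = dvh(80, 1)), 1)
  expect_lt(cohort_log_loss(ch1, lkb_params(1, 0.01, 20)), 1e-10)
})

test_that("log-loss stays finite over the whole box including m = 0", {
  ch <- toy_cohort(list(a = dvh(30, 1), b = dvh(60, 1)), c(0, 1))
  for (m in c(0, 1e-9, 0.5, 1)) {
    l <- cohort_log_loss(ch, lkb_params(1, m, 45))
    expect_true(is.finite(l))
    expect_gte(l, 0)
  }
})

test_that("gradient descent started at the truth stays at a good optimum", {
  sim <- simulate_cohorts(sim_config(n_train = 1000, n_test = 50, seed = 9))
  truth <- lkb_params(1, 0.55, 47)
  fit <- lkb_fit(sim$train, "gradient_descent", initial = truth, seed = 1)
  expect_true(fit$converged)
  expect_lte(fit$loss, cohort_log_loss(sim$train, truth) + 1e-10)
  # perturbed starts cannot do better than the loss reached from the truth
  perturbed <- lkb_fit(sim$train, "gradient_descent",
                       initial = lkb_params(3.5, 0.9, 110), seed = 1)
  expect_gte(perturbed$loss, fit$loss - 1e-6)
})

test_that("fixing n = 1 yields a two-parameter fit", {
  sim <- simulate_cohorts(sim_config(n_train = 150, n_test = 20, seed = 21))
  fit <- lkb_fit(sim$train, "gradient_descent",
                 initial = lkb_params(1, 0.5, 50), fixed = list(n = 1))
  expect_identical(fit$df, 2L)
  expect_equal(fit$params$n, 1)
  fit3 <- lkb_fit(sim$train, "gradient_descent",
                  initial = lkb_params(1, 0.5, 50))
  expect_identical(fit3$df, 3L)
})

test_that("unsafe n bounds are refused unless explicitly overridden", {
  sim <- simulate_cohorts(sim_config(n_train = 60, n_test = 20, seed = 2))
  b <- lkb_bounds()
  b$n[1] <- 0.001
  expect_error(lkb_fit(sim$train, "gradient_descent",
                       initial = lkb_params(1, 0.5, 50), bounds = b),
               "infinit")
  fit <- lkb_fit(sim$train, "gradient_descent",
                 initial = lkb_params(1, 0.5, 50), bounds = b,
                 allow_unsafe_bounds = TRUE)
  expect_s3_class(fit, "lkb_fit")
})

test_that("initial points outside bounds and unknown methods are rejected", {
  sim <- simulate_cohorts(sim_config(n_train = 60, n_test = 20, seed = 2))
  expect_error(lkb_fit(sim$train, "gradient_descent",
                       initial = lkb_params(3, 0.5, 150)), "outside")
  expect_error(lkb_fit(sim$train, "no_such_method"))
  expect_error(lkb_fit(sim$train, "gradient_descent"), "initial")
})

test_that("global optimizers are reproducible per seed", {
  sim <- simulate_cohorts(sim_config(n_train = 100, n_test = 20, seed = 31))
  f1 <- lkb_fit(sim$train, "differential_evolution", seed = 7,
                control = list(maxiter = 30))
  f2 <- lkb_fit(sim$train, "differential_evolution", seed = 7,
                control = list(maxiter = 30))
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$loss, f2$loss)
})

test_that("fit results serialize to JSON with the full metadata set", {
  sim <- simulate_cohorts(sim_config(n_train = 60, n_test = 20, seed = 2))
  fit <- lkb_fit(sim$train, "gradient_descent",
                 initial = lkb_params(1, 0.5, 50))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, tmp)
  x <- jsonlite::read_json(tmp)
  expect_setequal(
    names(x),
    c("params", "loss", "converged", "optimizer", "n_evaluations",
      "elapsed", "df", "seed", "bounds", "fixed"))
  expect_equal(x$params$d50, fit$params$d50)
})

test_that("a degenerate 1x1 landscape grid equals the pointwise loss", {
  sim <- simulate_cohorts(sim_config(n_train = 80, n_test = 20, seed = 13))
  g <- loss_landscape(sim$train, 1, 47, 0.55)
  expect_equal(nrow(g), 1L)
  expect_equal(g$loss, cohort_log_loss(sim$train, lkb_params(1, 0.55, 47)),
               tolerance = 1e-12)
})

test_that("landscape D50 gradient changes sign across the optimum column", {
  sim <- simulate_cohorts(sim_config(n_train = 500, n_test = 50, seed = 17))
  fit <- lkb_fit(sim$train, "differential_evolution", seed = 1,
                 control = list(maxiter = 100))
  d50s <- fit$params$d50 + c(-15, -5, 5, 15)
  g <- loss_landscape(sim$train, fit$params$n, d50s, fit$params$m)
  expect_lt(g$grad_d50[1], 0)
  expect_gt(g$grad_d50[4], 0)
})

test_that("loss is flat in n for uniform-dose DVHs", {
  ch <- toy_cohort(list(a = dvh(30, 1), b = dvh(60, 1)), c(0, 1))
  g <- loss_landscape(ch, c(0.05, 0.5, 1, 2), 45, 0.5)
  expect_true(all(abs(g$grad_n) < 1e-8))
  expect_equal(max(g$loss) - min(g$loss), 0, tolerance = 1e-12)
})

test_that("landscape refuses out-of-bounds nodes, naming them", {
  ch <- toy_cohort(list(a = dvh(30, 1), b = dvh(60, 1)), c(0, 1))
  expect_error(loss_landscape(ch, c(0.001, 1), 47, 0.5), "0.001")
  expect_error(loss_landscape(ch, 1, 150, 0.5), "150")
  expect_error(loss_landscape(ch, 1, 47, 0), "m_fixed")
})
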