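# two-batch feature fixture: batch b shifted and scaled relative to batch a
make_shifted_features <- function(n_per = 250, shift = 10, scale = 2, seed = 1) {
  withr::with_seed(seed, {
    xa <- cbind(dose = rnorm(n_per, 30, 4), age = rnorm(n_per, 60, 8),
                vol = rnorm(n_per, 20, 3))
    xb <- cbind(dose = rnorm(n_per, 30, 4) * scale + shift,
                age = rnorm(n_per, 60, 8), vol = rnorm(n_per, 20, 3))
    list(x = rbind(xa, xb), batch = rep(c("a", "b"), each = n_per))
  })
}

test_that("identical-distribution batches pass through essentially unchanged", {
  f <- make_shifted_features(shift = 0, scale = 1, seed = 4)
  m <- combat_fit(f$x, f$batch)
  expect_true(all(m$delta_star > 0))
  corrected <- combat_apply(m, f$x, f$batch)
  # changes bounded by the sampling noise of the batch-mean estimates
  sds <- apply(f$x, 2, sd)
  expect_true(all(abs(corrected - f$x) <
                    matrix(sds, nrow(f$x), 3, byrow = TRUE)))
  # grand means move only by the (small) imbalance of shrunk batch effects
  expect_lt(max(abs(colMeans(corrected) - colMeans(f$x)) / sds), 5e-3)
})

test_that("a +10 Gy shift with x2 scale is removed almost entirely", {
  f <- make_shifted_features(shift = 10, scale = 2, seed = 5)
  m <- combat_fit(f$x, f$batch)
  corrected <- combat_apply(m, f$x, f$batch)
  a <- f$batch == "a"
  gap_mean_before <- abs(mean(f$x[a, "dose"]) - mean(f$x[!a, "dose"]))
  gap_mean_after <- abs(mean(corrected[a, "dose"]) - mean(corrected[!a, "dose"]))
  gap_sd_before <- abs(sd(f$x[a, "dose"]) / sd(f$x[!a, "dose"]) - 1)
  gap_sd_after <- abs(sd(corrected[a, "dose"]) / sd(corrected[!a, "dose"]) - 1)
  expect_lt(gap_mean_after, 0.1 * gap_mean_before)
  expect_lt(gap_sd_after, 0.1 * gap_sd_before)
})

test_that("correction agrees element-wise with the reference EB implementation", {
  skip_if_not_installed("sva")
  f <- make_shifted_features(n_per = 40, shift = 10, scale = 2, seed = 6)
  m <- combat_fit(f$x, f$batch)
  corrected <- combat_apply(m, f$x, f$batch)
  ref <- t(suppressMessages(
    sva::ComBat(dat = t(f$x), batch = f$batch, par.prior = TRUE,
                prior.plots = FALSE)))
  expect_equal(unname(corrected), unname(ref), tolerance = 1e-6)
})

test_that("re-fitting on corrected data finds near-null batch effects", {
  f <- make_shifted_features(shift = 10, scale = 2, seed = 7)
  m <- combat_fit(f$x, f$batch)
  corrected <- combat_apply(m, f$x, f$batch)
  m2 <- combat_fit(corrected, f$batch)
  expect_true(all(abs(m2$gamma_star) < 0.2))
  expect_true(all(abs(m2$delta_star - 1) < 0.3))
})

test_that("after fit+apply, per-batch means agree within sampling error across seeds", {
  for (seed in 1:20) {
    f <- make_shifted_features(n_per = 50, shift = 8, scale = 1.5, seed = seed)
    m <- combat_fit(f$x, f$batch)
    corrected <- combat_apply(m, f$x, f$batch)
    a <- f$batch == "a"
    for (j in colnames(f$x)) {
      se <- sqrt(var(corrected[a, j]) / sum(a) + var(corrected[!a, j]) / sum(!a))
      expect_lt(abs(mean(corrected[a, j]) - mean(corrected[!a, j])), 2 * se)
    }
  }
})

test_that("degenerate inputs are refused with informative errors", {
  x <- cbind(f1 = rnorm(10), f2 = rnorm(10))
  expect_error(combat_fit(x, rep("only", 10)), "one batch")
  expect_error(combat_fit(x, c(rep("a", 8), "b", "b")), ">= 3")
  xz <- cbind(f1 = rnorm(10), const = rep(5, 10))
  expect_error(combat_fit(xz, rep(c("a", "b"), each = 5)), "const")
  expect_error(combat_fit(xz, rep(c("a", "b"), each = 5)), "zero variance")
})

test_that("unseen batches are refused at apply time", {
  f <- make_shifted_features(n_per = 20, seed = 8)
  m <- combat_fit(f$x, f$batch)
  expect_error(combat_apply(m, f$x[1:3, ], rep("c", 3)), "not seen")
})

test_that("a single feature is corrected without EB shrinkage", {
  f <- make_shifted_features(n_per = 40, shift = 10, scale = 2, seed = 9)
  x1 <- f$x[, "dose", drop = FALSE]
  m <- combat_fit(x1, f$batch)
  expect_false(m$eb_shrunk)
  corrected <- combat_apply(m, x1, f$batch)
  a <- f$batch == "a"
  expect_lt(abs(mean(corrected[a, 1]) - mean(corrected[!a, 1])), 1e-6)
})

test_that("combat model serializes to JSON", {
  f <- make_shifted_features(n_per = 20, seed = 10)
  m <- combat_fit(f$x, f$batch)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_combat_json(m, tmp)
  x <- jsonlite::read_json(tmp)
  expect_true(all(c("grand_mean", "var_pooled", "gamma_star", "delta_star",
                    "batches") %in% names(x)))
})
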