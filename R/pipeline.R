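#' Assemble and validate a study run configuration
#'
#' Exactly one of `simulation` (a [sim_config()]) or `input` (a list with
#' `train_dir` and `test_dir` pointing at [write_cohort()] directories) must
#' be supplied.
#'
#' @param simulation Optional [sim_config()] describing cohorts to simulate.
#' @param input Optional list(train_dir=, test_dir=) of cohort directories.
#' @param combat Apply ComBat harmonization to ML features (default TRUE).
#' @param optimizers LKB optimizers to run (default all three).
#' @param bounds LKB parameter box ([lkb_bounds()]).
#' @param lkb_control Optimizer control list passed to [lkb_fit()].
#' @param sweep_starts Multi-start sweep size (default 200; 0 disables).
#' @param landscape Landscape grid settings:
#'   `list(n_grid =, d50_grid =, m_fixed =)`; `NULL` disables.
#' @param ml_models Model ids to benchmark (default AB, LR, DT, GB).
#' @param ml_grids Optional named list overriding [default_grid()] per id.
#' @param folds Cross-validation folds for tuning (default 20).
#' @param seed Master seed for every stage.
#' @return A validated `run_config` object.
#' @export
run_config <- function(simulation = NULL, input = NULL, combat = TRUE,
                       optimizers = c("dual_annealing",
                                      "differential_evolution",
                                      "gradient_descent"),
                       bounds = lkb_bounds(), lkb_control = list(),
                       sweep_starts = 200L,
                       landscape = list(n_grid = seq(0.05, 2, length.out = 8),
                                        d50_grid = seq(20, 80, length.out = 8),
                                        m_fixed = 0.55),
                       ml_models = c("AB", "LR", "DT", "GB"),
                       ml_grids = NULL, folds = 20L, seed = 1L) {
  if (is.null(simulation) == is.null(input))
    stop("config error at {simulation|input}: exactly one must be supplied")
  if (!is.null(simulation) && !inherits(simulation, "sim_config"))
    stop("config error at simulation: must be a sim_config object")
  if (!is.null(input) &&
      (is.null(input$train_dir) || is.null(input$test_dir)))
    stop("config error at input: needs train_dir and test_dir")
  bad <- setdiff(optimizers,
                 c("dual_annealing", "differential_evolution",
                   "gradient_descent"))
  if (length(bad))
    stop(sprintf("config error at optimizers: unknown %s",
                 paste(bad, collapse = ", ")))
  bad <- setdiff(ml_models, ml_model_ids)
  if (length(bad))
    stop(sprintf("config error at ml_models: unknown %s",
                 paste(bad, collapse = ", ")))
  structure(list(
    simulation = simulation, input = input, combat = isTRUE(combat),
    optimizers = optimizers, bounds = bounds, lkb_control = lkb_control,
    sweep_starts = as.integer(sweep_starts), landscape = landscape,
    ml_models = ml_models, ml_grids = ml_grids, folds = as.integer(folds),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Simulate cohorts and write them with a manifest
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
simulate_to_files <- function(config, dir) {
  sim <- simulate_cohorts(config)
  write_simulation(sim, dir)
  write_manifest(dir)
  invisible(dir)
}

# manifest of every artifact with a content hash (md5)
write_manifest <- function(dir) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  rel <- substring(files, nchar(dir) + 2L)
  hashes <- unname(tools::md5sum(files))
  jsonlite::write_json(
    lapply(seq_along(rel), function(i)
      list(path = rel[i], md5 = hashes[i])),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

#' Run the full study pipeline
#'
#' Executes, in order: data (simulate or load), ComBat harmonization
#' diagnostic, LKB fits with every requested optimizer, the multi-start
#' convergence sweep, the loss-landscape grid, and the ML-vs-LKB benchmark.
#' Every stage logs its parameters and seed; a failing stage is recorded in
#' the report's `errors` and later independent stages still run. All
#' artifacts (JSON/CSV) are written under `output_dir` together with a
#' manifest of content hashes; with equal seeds, all non-timing content
#' reproduces exactly.
#'
#' @param config A [run_config()].
#' @param output_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return A list report: cohorts, LKB `fits`, `sweep`, `landscape`,
#'   `benchmark` table, ComBat diagnostic, per-stage `errors`, and the
#'   `output_dir`.
#' @export
run_study <- function(config, output_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      say("stage %s failed: %s", name, conditionMessage(e))
      NULL
    })
  }

  say("stage data (seed %d)", config$seed)
  data <- stage("data", {
    if (!is.null(config$simulation)) {
      sim <- simulate_cohorts(config$simulation)
      write_simulation(sim, file.path(output_dir, "data"))
      sim[c("train", "test")]
    } else {
      list(train = read_cohort(config$input$train_dir),
           test = read_cohort(config$input$test_dir))
    }
  })
  if (is.null(data)) stop("cannot continue without cohorts")
  train <- data$train
  test <- data$test

  combat_diag <- stage("combat", {
    x_tr <- build_features(train)
    x_te <- build_features(test)
    gap_before <- abs(mean(x_tr[, "mean_dose"]) - mean(x_te[, "mean_dose"]))
    out <- list(gap_before = gap_before, gap_after = gap_before,
                applied = FALSE)
    if (config$combat) {
      xall <- rbind(x_tr, x_te)
      batch <- c(as.character(train$patients$batch),
                 as.character(test$patients$batch))
      continuous <- names(which(apply(xall, 2L, function(v)
        length(unique(v)) > 2L)))
      cm <- combat_fit(xall[, continuous, drop = FALSE], batch)
      corr <- combat_apply(cm, xall[, continuous, drop = FALSE], batch)
      ntr <- nrow(x_tr)
      out$gap_after <- abs(mean(corr[seq_len(ntr), "mean_dose"]) -
                             mean(corr[-seq_len(ntr), "mean_dose"]))
      out$applied <- TRUE
      write_combat_json(cm, file.path(output_dir, "combat_model.json"))
    }
    say("mean-dose centre gap: %.3f Gy before, %.3f Gy after ComBat",
        out$gap_before, out$gap_after)
    out
  })

  fits <- list()
  for (opt in config$optimizers) {
    say("stage lkb_fit/%s", opt)
    fits[[opt]] <- stage(paste0("lkb_fit_", opt), {
      init <- if (opt == "gradient_descent") {
        b <- config$bounds
        lkb_params(mean(b$n), mean(b$m), mean(b$d50))
      } else NULL
      fit <- lkb_fit(train, method = opt, initial = init,
                     bounds = config$bounds, seed = config$seed,
                     control = config$lkb_control)
      write_fit_json(fit, file.path(output_dir,
                                    sprintf("lkb_fit_%s.json", opt)))
      fit
    })
  }

  sweep <- NULL
  if (config$sweep_starts > 0L) {
    say("stage sweep (%d starts)", config$sweep_starts)
    sweep <- stage("sweep", {
      sw <- run_sweep(train, test, n_starts = config$sweep_starts,
                      bounds = config$bounds, seed = config$seed,
                      force = TRUE)
      write_sweep(sw, file.path(output_dir, "sweep_records.csv"),
                  file.path(output_dir, "sweep_summary.json"))
      sw
    })
  }

  landscape <- NULL
  if (!is.null(config$landscape)) {
    say("stage landscape")
    landscape <- stage("landscape", {
      ls <- config$landscape
      grid <- loss_landscape(train, ls$n_grid, ls$d50_grid, ls$m_fixed,
                             bounds = config$bounds)
      utils::write.csv(grid, file.path(output_dir, "landscape.csv"),
                       row.names = FALSE)
      grid
    })
  }

  bench <- NULL
  if (length(config$ml_models)) {
    say("stage benchmark (%s)", paste(config$ml_models, collapse = ", "))
    bench <- stage("benchmark", {
      global <- Filter(function(f) !is.null(f) && f$converged &&
                         f$optimizer != "gradient_descent", fits)
      if (!length(global))
        global <- Filter(function(f) !is.null(f) && f$converged, fits)
      if (!length(global))
        stop("no converged LKB fit available for the benchmark row")
      best <- global[[which.min(vapply(global, `[[`, numeric(1), "loss"))]]
      specs <- lapply(config$ml_models, function(id) {
        grid <- if (!is.null(config$ml_grids[[id]]))
          config$ml_grids[[id]] else default_grid(id)
        model_spec(id, grid = grid, folds = config$folds,
                   seed = config$seed)
      })
      rep <- benchmark(train, test, specs, best, combat = config$combat,
                       seed = config$seed)
      write_benchmark(rep, file.path(output_dir, "benchmark.csv"),
                      file.path(output_dir, "benchmark.json"))
      rep
    })
  }

  write_manifest(output_dir)
  list(train = train, test = test, fits = fits, sweep = sweep,
       landscape = landscape, benchmark = bench, combat = combat_diag,
       errors = errors, output_dir = output_dir)
}
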