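#' Patient cohort
#'
#' Bundle a patient table with one differential DVH per patient. The table
#' must have columns `patient_id` (unique), `batch` (centre identifier) and
#' `toxicity` (binary 0/1 outcome); any further columns are treated as
#' covariates. Per-patient log-dose and log-volume matrices are precomputed
#' at construction so that cohort-level generalized-mean-dose evaluation is a
#' single vectorized log-sum-exp, which keeps likelihood evaluation cheap
#' inside the optimizers.
#'
#' @param patients A data frame with columns `patient_id`, `batch`,
#'   `toxicity` and optional covariate columns.
#' @param dvhs A list of [dvh] objects, one per row of `patients`, named by
#'   `patient_id` (or in row order if unnamed).
#' @return An object of class `ntcp_cohort`.
#' @export
cohort <- function(patients, dvhs) {
  stopifnot(is.data.frame(patients))
  req <- c("patient_id", "batch", "toxicity")
  if (!all(req %in% names(patients)))
    stop("patients table must have columns patient_id, batch, toxicity")
  if (anyDuplicated(patients$patient_id))
    stop("patient_id values must be unique")
  if (!all(patients$toxicity %in% c(0, 1)))
    stop("toxicity must be binary 0/1")
  n <- nrow(patients)
  if (n < 1L) stop("cohort must contain at least one patient")
  if (length(dvhs) != n)
    stop("need exactly one DVH per patient")
  if (!is.null(names(dvhs))) {
    if (!setequal(names(dvhs), as.character(patients$patient_id)))
      stop("names of dvhs must match patient_id values")
    dvhs <- dvhs[as.character(patients$patient_id)]
  }
  ok <- vapply(dvhs, inherits, logical(1), what = "dvh")
  if (!all(ok)) stop("every element of dvhs must be a dvh object")
  names(dvhs) <- as.character(patients$patient_id)

  # ragged DVHs packed into rectangular log matrices, padded with -Inf volume
  nbins <- vapply(dvhs, function(h) length(h$doses), integer(1))
  k <- max(nbins)
  logv <- matrix(-Inf, n, k)
  logd <- matrix(0, n, k)
  for (i in seq_len(n)) {
    h <- dvhs[[i]]
    use <- h$volumes > 0 & h$doses > 0
    m <- sum(use)
    if (m > 0L) {
      logv[i, seq_len(m)] <- log(h$volumes[use])
      logd[i, seq_len(m)] <- log(h$doses[use])
    }
  }
  structure(
    list(patients = patients, dvhs = dvhs, .logv = logv, .logd = logd),
    class = "ntcp_cohort"
  )
}

#' @export
print.ntcp_cohort <- function(x, ...) {
  p <- x$patients
  cat(sprintf("NTCP cohort: %d patients, %d centre(s), toxicity prevalence %.3f\n",
              nrow(p), length(unique(p$batch)), mean(p$toxicity)))
  cov <- setdiff(names(p), c("patient_id", "batch", "toxicity"))
  if (length(cov)) cat("covariates:", paste(cov, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.ntcp_cohort <- function(x) nrow(x$patients)

#' Generalized mean dose for every patient in a cohort
#'
#' Vectorized log-space evaluation of [generalized_mean_dose()] across all
#' patients at a common `n`.
#'
#' @param ch An [cohort()] object.
#' @param n Volume-dependence parameter (`>= n_floor`).
#' @param n_floor Smallest admissible `n` (default `1e-3`).
#' @return Numeric vector of GMD values in Gy, one per patient, in table
#'   order.
#' @export
cohort_gmd <- function(ch, n, n_floor = 1e-3) {
  stopifnot(inherits(ch, "ntcp_cohort"))
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n))
    stop("n must be a single finite number")
  if (n < n_floor)
    stop(sprintf("n = %g is below the evaluation floor %g", n, n_floor))
  a <- ch$.logv + ch$.logd / n
  # row maxima via max.col (C-level); ties irrelevant for the value
  m <- a[cbind(seq_len(nrow(a)), max.col(a, ties.method = "first"))]
  out <- numeric(nrow(a))
  fin <- is.finite(m)
  if (any(fin)) {
    am <- a[fin, , drop = FALSE] - m[fin]
    out[fin] <- exp(n * (m[fin] + log(rowSums(exp(am)))))
  }
  out
}

#' Split covariate columns out of a cohort table
#' @noRd
cohort_covariates <- function(ch) {
  p <- ch$patients
  p[, setdiff(names(p), c("patient_id", "batch", "toxicity")), drop = FALSE]
}

#' Write a cohort to disk
#'
#' Writes the patient table as `cohort.csv` and one differential DVH CSV per
#' patient (`dvh_<patient_id>.csv`) into `dir`.
#'
#' @param ch An [cohort()] object.
#' @param dir Output directory; created if missing.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(ch, dir) {
  stopifnot(inherits(ch, "ntcp_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(ch$patients, file.path(dir, "cohort.csv"),
                   row.names = FALSE, quote = FALSE)
  for (id in names(ch$dvhs))
    write_dvh(ch$dvhs[[id]], file.path(dir, paste0("dvh_", id, ".csv")))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `cohort.csv` and per-patient `dvh_<id>.csv`
#'   files.
#' @return An [cohort()] object.
#' @export
read_cohort <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  dvhs <- lapply(as.character(tab$patient_id), function(id)
    read_dvh(file.path(dir, paste0("dvh_", id, ".csv"))))
  names(dvhs) <- as.character(tab$patient_id)
  cohort(tab, dvhs)
}
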