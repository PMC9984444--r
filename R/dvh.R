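#' Differential dose-volume histogram
#'
#' Construct and validate a differential dose-volume histogram (DVH): a set of
#' `(dose, fractional volume)` pairs describing how the volume of one organ of
#' one patient is distributed over dose. Doses are bin-centre values in Gy;
#' volumes are unitless fractions summing to 1.
#'
#' @param doses Numeric vector of bin-centre doses in Gy, strictly increasing,
#'   all non-negative.
#' @param volumes Numeric vector of fractional volumes, same length as
#'   `doses`, all non-negative, summing to 1 within `1e-6`.
#'
#' @return An object of class `dvh`: a list with elements `doses` and
#'   `volumes`.
#' @examples
#' h <- dvh(c(20, 60), c(0.5, 0.5))
#' mean_dose(h)
#' @export
dvh <- function(doses, volumes) {
  doses <- as.numeric(doses)
  volumes <- as.numeric(volumes)
  if (length(doses) < 1L || length(doses) != length(volumes))
    stop("doses and volumes must be non-empty vectors of equal length")
  if (anyNA(doses) || anyNA(volumes))
    stop("doses and volumes must not contain missing values")
  if (any(doses < 0))
    stop("doses must all be >= 0")
  if (length(doses) > 1L && any(diff(doses) <= 0))
    stop("doses must be strictly increasing")
  if (any(volumes < 0))
    stop("volumes must all be >= 0")
  s <- sum(volumes)
  if (abs(s - 1) > 1e-6)
    stop(sprintf("fractional volumes must sum to 1 (got %.8f)", s))
  structure(list(doses = doses, volumes = volumes), class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("Differential DVH: %d bins, dose range [%.3g, %.3g] Gy, mean dose %.3g Gy\n",
              length(x$doses), min(x$doses), max(x$doses), mean_dose(x)))
  invisible(x)
}

#' Read a DVH from CSV
#'
#' Reads a per-patient DVH file with header columns `dose_gy,volume`. A
#' `differential` file is taken as-is; a `cumulative` file (volume
#' non-increasing, starting at 1) is converted to differential form by
#' successive differences, with the mass of each step assigned to the bin
#' midpoint. Volume sums within 1% of 1 are renormalized; larger deviations
#' are an error.
#'
#' @param path Path to a CSV file with columns `dose_gy` and `volume`.
#' @param dialect Either `"differential"` (default) or `"cumulative"`.
#' @return A [dvh] object (always differential).
#' @export
read_dvh <- function(path, dialect = c("differential", "cumulative")) {
  dialect <- match.arg(dialect)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("failed to parse DVH CSV '%s': %s", path, conditionMessage(e)))
  )
  if (!all(c("dose_gy", "volume") %in% names(df)))
    stop(sprintf("DVH CSV '%s' must have header columns dose_gy,volume", path))
  d <- as.numeric(df$dose_gy)
  v <- as.numeric(df$volume)
  if (anyNA(d) || anyNA(v))
    stop(sprintf("DVH CSV '%s' contains non-numeric or missing entries", path))
  if (any(d < 0) || any(v < 0))
    stop(sprintf("DVH CSV '%s' contains negative dose or volume", path))
  if (dialect == "cumulative") {
    if (length(d) < 2L)
      stop("a cumulative DVH needs at least two rows")
    if (any(diff(v) > 1e-12))
      stop("cumulative DVH volume column must be non-increasing")
    if (abs(v[1L] - 1) > 0.01)
      stop(sprintf("cumulative DVH must start at volume 1 (got %.6f)", v[1L]))
    vols <- -diff(v)
    mids <- (d[-1L] + d[-length(d)]) / 2
    keep <- vols > 0
    d <- mids[keep]
    v <- vols[keep]
    # residual volume above the last dose level stays unassigned only if zero
    if (v[length(v)] < 0) stop("cumulative DVH conversion produced negative mass")
  }
  s <- sum(v)
  if (abs(s - 1) > 0.01)
    stop(sprintf("DVH volumes sum to %.6f; more than 1%% from 1 (normalization error)", s))
  dvh(d, v / s)
}

#' Write a DVH to CSV
#'
#' Writes the differential form with header `dose_gy,volume`, round-tripping
#' with [read_dvh()].
#'
#' @param h A [dvh] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dvh <- function(h, path) {
  stopifnot(inherits(h, "dvh"))
  utils::write.csv(
    data.frame(dose_gy = h$doses, volume = h$volumes),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Generalized mean dose (EUD)
#'
#' The generalized mean dose of a differential DVH with volume-dependence
#' parameter `n`:
#' \deqn{\mathrm{GMD} = \Big(\sum_i v_i D_i^{1/n}\Big)^{n},}
#' the power mean with exponent `1/n`, equal to the equivalent uniform dose.
#' At `n = 1` it is the arithmetic mean dose; as `n` decreases towards 0 it
#' approaches the maximum dose.
#'
#' Evaluation is carried out entirely in log space (a log-sum-exp over
#' `log(v_i) + (1/n) log(D_i)`), so no intermediate overflows even at
#' `n = 0.01` with doses of tens of Gy, where a direct evaluation would raise
#' doses to the power 100. Small `n` remains numerically hazardous in
#' principle, so values of `n` below `n_floor` are refused rather than
#' clamped.
#'
#' Zero-dose bins contribute nothing (the limit of \eqn{v D^{1/n}} as
#' \eqn{D \to 0} is 0 for positive `n`) and are excluded from the sum; a DVH
#' whose every positive-volume bin has zero dose returns 0 by convention.
#'
#' @param h A [dvh] object.
#' @param n Volume-dependence parameter; must be `>= n_floor`.
#' @param n_floor Smallest admissible `n` (default `1e-3`).
#' @return The generalized mean dose in Gy, bounded by the minimum and
#'   maximum dose over positive-volume bins.
#' @examples
#' h <- dvh(c(20, 60), c(0.5, 0.5))
#' generalized_mean_dose(h, 1)     # arithmetic mean: 40
#' generalized_mean_dose(h, 0.01)  # close to the maximum dose
#' @export
generalized_mean_dose <- function(h, n, n_floor = 1e-3) {
  stopifnot(inherits(h, "dvh"))
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n))
    stop("n must be a single finite number")
  if (n < n_floor)
    stop(sprintf(
      "n = %g is below the evaluation floor %g: such values risk computational infinities in the power-mean evaluation",
      n, n_floor))
  pos <- h$volumes > 0
  if (!any(pos)) stop("all volumes are zero; DVH carries no mass")
  d <- h$doses[pos]
  v <- h$volumes[pos]
  nz <- d > 0
  if (!any(nz)) return(0)
  d <- d[nz]; v <- v[nz]
  a <- log(v) + log(d) / n
  m <- max(a)
  exp(n * (m + log(sum(exp(a - m)))))
}

#' Mean dose of a DVH
#'
#' The volume-weighted arithmetic mean dose, \eqn{\sum_i v_i D_i}; identical
#' to [generalized_mean_dose()] at `n = 1`.
#'
#' @param h A [dvh] object.
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(h) {
  stopifnot(inherits(h, "dvh"))
  sum(h$doses * h$volumes)
}

#' Maximum dose of a DVH
#'
#' The highest dose bin carrying positive volume.
#'
#' @param h A [dvh] object.
#' @return Maximum dose in Gy.
#' @export
max_dose <- function(h) {
  stopifnot(inherits(h, "dvh"))
  pos <- h$volumes > 0
  if (!any(pos)) return(0)
  max(h$doses[pos])
}
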