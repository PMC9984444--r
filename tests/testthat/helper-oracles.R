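# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the GMD oracle evaluates the power mean directly
# (no log-space), the metric oracles enumerate pairs / sum terms by hand.

# Direct power-mean evaluation. Valid as an oracle whenever doses^(1/n) stays
# inside double range (doses <= 80 Gy and n >= 0.01 keep every term below
# ~1e190); accuracy ~1e-13 relative there.
gmd_direct <- function(doses, volumes, n) {
  keep <- volumes > 0 & doses > 0
  if (!any(keep)) return(0)
  sum(volumes[keep] * doses[keep]^(1 / n))^n
}

brier_brute <- function(p, y) {
  s <- 0
  for (i in seq_along(p)) s <- s + (p[i] - y[i])^2
  s / length(p)
}

# exhaustive positive/negative pair enumeration, ties count one half
auc_brute <- function(p, y) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

accuracy_brute <- function(p, y, thr = 0.5) {
  ok <- 0
  for (i in seq_along(p))
    ok <- ok + as.integer((p[i] >= thr) == (y[i] == 1))
  ok / length(p)
}

# random valid differential DVH on a bounded dose range
random_dvh <- function(n_bins = NULL, max_dose = 80) {
  if (is.null(n_bins)) n_bins <- sample(2:50, 1)
  d <- sort(runif(n_bins, 0.5, max_dose))
  while (any(diff(d) <= 0)) d <- sort(runif(n_bins, 0.5, max_dose))
  v <- runif(n_bins)
  v <- v / sum(v)
  dvh(d, v)
}

# small deterministic cohort built from explicit DVHs and labels
toy_cohort <- function(dvhs, labels, batch = "c1") {
  dvhs <- unname(dvhs)
  n <- length(dvhs)
  cohort(
    data.frame(patient_id = sprintf("p%02d", seq_len(n)),
               batch = batch, toxicity = labels,
               stringsAsFactors = FALSE),
    dvhs
  )
}
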