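# ntcpbench

Normal tissue complication probability (NTCP) modelling for radiotherapy
outcomes research: the Lyman–Kutcher–Burman (LKB) dose–response model, its
well-known fitting pathologies made measurable, and a fair benchmark of the
model against standard machine-learning classifiers — with cross-centre
batch-effect harmonization and a seeded synthetic cohort generator so the
entire study runs end-to-end without access to clinical registries.

Intended users: medical physicists and outcomes researchers who fit
dose–response models to dose–volume histogram (DVH) data, and
methodologists studying why those fits misbehave.

## The model

A differential DVH — pairs $(D_i, v_i)$ of bin-centre dose (Gy) and
fractional volume — is collapsed to the generalized mean dose

$$\mathrm{GMD}(n) = \Big(\sum_i v_i\,D_i^{1/n}\Big)^{n},$$

the power mean with exponent $1/n$ (mean dose at $n = 1$, maximum dose as
$n \to 0$). The complication probability is a probit in the scaled dose
excess over the 50%-complication dose:

$$\mathrm{NTCP} = \Phi\!\left(\frac{\mathrm{GMD} - D_{50}}{m\,D_{50}}\right).$$

The package fits $(n, m, D_{50})$ to binary toxicity labels by mean
log-loss, with three optimizers (bounded quasi-Newton descent with
central-difference gradients; seeded differential evolution; a seeded
annealing scheme with local refinement), quantifies the model's multi-basin
convergence behaviour with multi-start sweeps and $(n, D_{50})$
loss-landscape grids, harmonizes scalar features across treatment centres
with parametric empirical-Bayes ComBat, and scores the LKB model beside
tuned AdaBoost / logistic regression / decision tree / gradient boosting
classifiers by Brier score, ROC-AUC and accuracy on train and test splits.

All dosimetry is evaluated in log space, so the power mean cannot overflow
even at $n = 0.01$; bounds that admit smaller $n$ are refused rather than
silently clamped.

## Worked example

```r
library(ntcpbench)

# two-centre synthetic study: 194 training / 76 testing patients,
# toxicity generated from the truth (n = 1, m = 0.55, D50 = 47 Gy)
sim <- simulate_cohorts(sim_config(seed = 42))
sim$train
#> NTCP cohort: 194 patients, 1 centre(s), toxicity prevalence 0.335
#> covariates: age, chemo

fit <- lkb_fit(sim$train, method = "differential_evolution", seed = 1,
               control = list(maxiter = 150))
fit
#> LKB fit (differential_evolution): converged
#> LKB parameters: n = 4, m = 0.5391, D50 = 46.89 Gy
#> mean log-loss 0.556224 nats | 3 free parameter(s) | 2340 evaluations | 0.95 s

p_test <- ntcp(cohort_gmd(sim$test, fit$params$n), fit$params)
y_test <- sim$test$patients$toxicity
c(auc = roc_auc(p_test, y_test), brier = brier(p_test, y_test))
#> test ROC-AUC 0.705 | Brier 0.168

sw <- run_sweep(sim$train, sim$test, n_starts = 200, seed = 1, force = TRUE)
sw
#> Convergence sweep: 200 starts | failed 0.00% | non-predictive 1.50% | predictive 98.50%
#> best loss 0.556224 nats | converged-fit test AUC min/median/max = 0.500/0.705/0.705
```

Reading the output: the global fit recovers `m` and `D50` near the
generating truth while `n` lands at a bound — on this cohort the profile
likelihood in `n` is nearly flat, the parameter-ambiguity face of the LKB
model (note the fitted loss equals the sweep's best). The sweep shows the
other face: a few percent of local-descent starts strand in degenerate
basins whose constant predictions are non-predictive (test ROC-AUC 0.5),
while the global optimizer is unaffected. `loss_landscape()` tabulates the
loss and its gradient over an $(n, D_{50})$ grid to visualize exactly this.

The full study — simulate/load, ComBat, all LKB fits, sweep, landscape,
classifier benchmark, manifested JSON/CSV outputs — runs in one call:

```r
report <- run_study(run_config(simulation = sim_config(seed = 1)), "out/")
```

or from the shell via the thin CLI
(`Rscript inst/cli/ntcpbench.R run-study --out out --seed 1`; subcommands
`simulate`, `fit-lkb`, `sweep`, `landscape`, `combat`, `benchmark`,
`run-study`).

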