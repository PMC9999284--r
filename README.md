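# ordlmi

Longitudinal measurement invariance (LMI) and latent-distribution
diagnostics for repeatedly administered ordinal symptom inventories
(GAD-7- and BDI-style questionnaires), aimed at psychometricians and
treatment-outcome researchers who need to know whether observed symptom
change reflects latent change — and how much the answer depends on the
model's normality assumptions.

## What it implements

Each ordinal item response is modeled by a liability-threshold link:
`y*_ist = λ_it θ_st + ε_ist`, `ε ~ N(0, ψ_it)`, with the recorded category
the count of thresholds `τ_ict` below `y*`.  On top of this the package
provides:

* **The nested LMI sequence** (configural → loadings → threshold →
  unique-factor) for `I` items × `T` sessions × `C` categories, built as an
  explicit parameter ledger with exact degrees-of-freedom accounting
  (`build_model()`, `delta_df()`), fitted by diagonally weighted least
  squares on polychoric correlations and thresholds (`fit_dwls()`,
  `fit_lmi_sequence()`), plus the fixed-latent-variance variant and the
  fit-preserving constant-SD reparameterization.
* **Fit evaluation**: chi-square difference tests, RMSEA-based
  *equivalence* tests (null = "fit is poor"; small p supports invariance),
  RMSEA, CFI, SRMR (`fit_evaluation_table()`).
* **Ordinal associations**: two-step ML polychoric correlations and a
  likelihood-ratio test of latent bivariate normality per item pair
  (`estimate_polychoric()`, `bivariate_normality_test()`,
  `polychoric_matrix()`).
* **Davidian-curve IRT**: graded-response models with a
  squared-polynomial × normal latent density estimated by EM, order
  selected by Hannan–Quinn (`fit_graded_davidian()`, `select_order()`,
  `density_summary()`).
* **Zero-inflation diagnostics** on endorsed-symptom counts, observed and
  model-implied (`zero_inflation_score_test()`,
  `model_implied_count_test()`).
* **Treatment-effect comparison**: latent vs sum-score standardized
  trajectories, effect ratios, and tail risk ratios
  (`standardized_trajectories()`, `tail_risk_ratio()`).
* **A synthetic-cohort generator** (`synthetic_config()`,
  `generate_cohort()`) producing liability-threshold ordinal data with
  configurable latent trajectories (normal, shifted-log-normal, or
  Davidian-shaped), AR(1) cross-session correlation, and monotone dropout
  following a retention schedule or a logistic hazard — so the whole
  pipeline is testable without clinical register data.

See `vignettes/methods.Rmd` for the model details, identification scheme,
and every numerical choice.

## Worked example

```r
library(ordlmi)

cfg <- synthetic_config(2000, 7, 4,
                        latent_means = c(0, -0.5, -1, -1.39),
                        latent_variances = c(1, 1.5, 2, 3),
                        loadings = rep(0.8, 7), seed = 11)
dat  <- generate_cohort(cfg)
smp  <- polychoric_matrix(dat)
fit  <- fit_dwls(smp, build_model("unique_factor", 7, 4, 4))
traj <- standardized_trajectories(dat, fit)

round(traj$effect[traj$estimator == "latent_lmi"], 3)
#> [1]  0.000 -0.501 -0.967 -1.484
round(traj$effect[traj$estimator == "sum_score"], 3)
#> [1]  0.000 -0.339 -0.570 -0.680
round(constant_sd_reparameterization(fit)$alpha, 3)
#> [1]  0.000 -0.421 -0.699 -0.819
```

The cohort was generated with latent variance tripling across sessions.
The invariance fit (latent mean in session-1 SD units) reports a 1.48-unit
decrease, more than twice the sum-score estimate (0.68), because the model
absorbs the growing zero-inflation of the ordinal data into a growing
latent variance; the constant-SD reparameterization — identical fit,
per-session-SD units — lands back near the sum score (0.82).  The implied
tail risk ratio

```r
est <- fit$estimates
round(tail_risk_ratio(est$alpha[1], est$phi[1, 1],
                      est$alpha[4], est$phi[4, 4], c(1, 2.5, 3.5)), 2)
#> [1]  0.54  2.25 12.83
```

is below 1 at moderate cutoffs but far above 1 in the extreme tail: the
fitted model simultaneously predicts fewer moderate cases and *more*
extreme-severity cases after treatment.

The four-level df ledger reproduces the invariance-step df changes for the
two instrument designs exactly:

```r
sapply(c("configural", "loadings", "threshold", "unique_factor"),
       function(lv) model_df(build_model(lv, 7, 13, 4)))
#> configural  loadings  threshold  unique_factor
#>       7943      8015       8171           8255   # steps: 72, 156, 84
```

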