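# trajmix — trajectory-shape mixture models for longitudinal growth data

`trajmix` clusters longitudinal growth trajectories by **shape** rather
than level, and relates the resulting growth-pattern groups to baseline
exposures. It was built for the kind of epidemiological question posed by
five-visit childhood BMI cohorts — *is prenatal chemical exposure
associated with how a child's BMI develops between ages 2 and 9?* — where
standard repeated-measures mixtures mostly rediscover that some children
are heavier than others.

## The method

1. **Level removal.** Each subject's observed mean outcome is subtracted
   from their measurements (`center_trajectories()`), so two children with
   the same growth *pattern* at different BMI levels become equivalent.
2. **Shape mixture.** The centered vectors `y_i` at visit ages `t_i` are
   modeled as a K-component multivariate Gaussian mixture

   `f(y_i | t_i, z_i) = Σ_k π_k(z_i) · N(y_i; X_i β_k, Σ_k)`

   where `X_i` is a quadratic B-spline basis (one internal knot at the
   median observed age, dimension 4), `Σ_k` is a working covariance —
   independence `σ_k² I` or exponential `σ_k² exp(−|t_s−t_u|/φ_k)` — and
   the membership probabilities `π_k(z)` follow a multinomial logit in
   baseline risk factors `z` (a *concomitant-variable* mixture).
   Estimation is multi-start EM (`fit_em()`).
3. **Model selection.** `select_model()` minimizes
   `BIC = −2·loglik + d·log(n_subjects)` over K ∈ {2,…,5} × {independence,
   exponential}; subjects are classified by maximum posterior probability
   (`classify()`).
4. **Association.** With K fixed, each exposure enters the concomitant
   model (unadjusted, then adjusted for confounders) and the full mixture
   is re-estimated (`refit_with_covariates()`). Effects are reported as
   **relative risk ratios** — for group j versus the flat reference group
   K, `RRR_j = exp(δ·γ_j)`, the membership-probability ratio under a
   δ-unit covariate increase (δ = 1 on a log10 exposure is a ten-fold
   concentration increase) — with 95% Wald CIs from the observed
   information of the full mixture likelihood (`rrr()`, `wald_ci()`).

Because the cohort data this method targets are restricted, the package
ships a synthetic-cohort generator (`simulate_cohort()`,
`default_growth_scenario()`) that reproduces the study's statistical
skeleton — five nominal visits, a ≥4-visit inclusion rule, four trajectory
shapes (linear riser; rise from age 4–5; rise from age 6–7; flat), Normal
level offsets, and log10 serum exposures shifting group membership — so
every stage is testable end to end with known truth.

## Worked example

```r
library(trajmix)

co <- simulate_cohort(default_growth_scenario(seed = 11, n_subjects = 250))
cp <- center_trajectories(co$panel)
sel <- select_model(cp, seed = 3)
sel
#> <model_selection> BIC grid:
#>  K     cov_kind    loglik n_params      bic converged
#>  2 independence -1614.402       11 3289.540      TRUE
#>  3 independence -1385.977       17 2865.819      TRUE
#>  4 independence -1287.823       23 2702.639      TRUE
#>  5 independence -1279.505       29 2719.133      TRUE
#>  2  exponential -1570.478       13 3212.735      TRUE
#>  3  exponential -1384.585       20 2879.599      TRUE
#>  4  exponential -1287.814       27 2724.708      TRUE
#>  5  exponential -1281.806       34 2751.343      TRUE
#> selected: K = 4, independence covariance (BIC = 2702.64)
```

BIC recovers the generator's four groups with the independence working
structure (the grid above is the output for these seeds; other seeds give
the same selection with slightly different numbers in 9 of 10 cases).
Group 1 is the steepest riser, group 4 the flat
reference — the label order is fixed by the fitted curve value at age 9.
Classification against the generator's true labels, after optimal label
matching, agrees for ~95–97% of subjects at this sample size, and the
posterior probabilities are well separated — in this synthetic cohort
under 5% of each group's posteriors fall in the uncertain band
(0.1, 0.9) reported by `classify()`.

Associations with a ten-fold exposure increase:

```r
des <- concomitant_design(co$baseline, exposures = "log10_ppDDE",
                          confounders = c("years_usa", "mat_bmi",
                                          "birth_weight_kg",
                                          "breastfeed_months"))
fit <- refit_with_covariates(cp, des, K = 4, cov_kind = "independence",
                             seed = 7, base_fit = sel$fit)
wald_ci(fit, "log10_ppDDE")
#>   group   rrr ci_low ci_high ...
```

returns one RRR row per group 1..3 versus the flat group 4 with
log-symmetric 95% CIs. `adjusted_and_unadjusted()` assembles the full
per-exposure, per-sex, adjusted/unadjusted table; `interaction_scan()`
screens exposure × modifier terms one at a time; `run_pipeline()` runs
everything (inclusion filter → sex stratification → centering → BIC
selection → classification → association tables → sensitivity refits) from
a single seeded config and writes CSV outputs plus a manifest.

The scripts under `analysis/` run the same workflow as a narrated
sequence: `01_simulate.R` (cohort), `02_model_selection.R` (BIC grid,
posteriors, curves), `03_associations.R` (RRR, sensitivity, interactions),
`04_report.R` (consolidated report tables under `results/`).

## Package layout

- `R/` — panel I/O and preprocessing, the synthetic-cohort generator, the
  spline/covariance/EM core, BIC selection and classification, the
  association layer, and the pipeline orchestrator.
- `tests/testthat/` — unit tests per module plus `test-acceptance.R`, the
  end-to-end property suite (EM monotonicity, oracle equivalence against
  direct numerical maximization, shift invariance, selection/recovery
  studies).
- `vignettes/trajectory-shape-mixtures.Rmd` — the model, its assumptions,
  every tunable default and why, and known limitations.
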