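---
title: "Clustering growth trajectories by shape: the trajmix model and its design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering growth trajectories by shape: the trajmix model and its design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Longitudinal studies of childhood growth typically record an outcome such
as BMI (kg/m², weight over height squared) at a handful of nominal visit
ages — here five visits at roughly 2, 3.5, 5, 7 and 9 years — and ask
whether early-life risk factors (for example, lipid-adjusted maternal serum
concentrations of organochlorine pesticides, in ng/g lipid) are associated
with *how* a child grows, not just how heavy the child is. Standard
finite-mixture clustering of repeated measures groups children mostly by
their BMI *level*, because the between-child variance in level dwarfs the
variance between trajectory shapes. `trajmix` implements the transformed
mixture approach: subtract each child's own mean outcome first, then
cluster the centered curves.

## Model

Let $y_i$ be child $i$'s centered outcome vector at visit ages $t_i$ and
$z_i$ the baseline covariate vector. The density is the concomitant-variable
mixture

$$f(y_i \mid t_i, z_i) \;=\; \sum_{k=1}^{K} \pi_k(z_i)\,
\phi\!\left(y_i;\; X_i\beta_k,\; \Sigma_k(t_i)\right),$$

with three ingredients:

* **Group mean curves.** $X_i$ is a quadratic B-spline basis evaluated at
  the child's visit ages, with one internal knot at the median pooled
  observed age and boundary knots at the observed age range — a
  4-dimensional curve space per group (`build_spline_basis()`). The basis
  includes the implicit intercept (partition of unity), so no separate
  intercept column is added; on centered data a free intercept would be
  nearly redundant anyway.
* **Within-subject covariance.** Either *independence*,
  $\Sigma_k = \sigma_k^2 I$, or *exponential*,
  $\Sigma_{k,su} = \sigma_k^2 \exp(-|t_s - t_u|/\phi_k)$, both with
  constant variance across visits and parameters specific to each group.
* **Concomitant membership model.** $\pi_k(z) =
  \exp(\eta_k)/\sum_j \exp(\eta_j)$ with $\eta_k = z^\top\gamma_k$ for
  $k < K$ and $\eta_K = 0$: a multinomial logit with the last (flattest)
  group as reference.

A deliberate and important compromise, inherited from the transformed
approach itself: exact centering makes the true covariance of a centered
vector rank-deficient (the centered values sum to zero, inducing
off-diagonal correlation $-\sigma^2/m$ for a child with $m$ visits). The
independence and exponential structures are *working* models fit to the
transformed data; neither can represent that negative equicorrelation. The
consequences show up in model selection under a null (see *Limitations*).

## Estimation

`fit_em()` maximizes the observed-data log-likelihood by an
expectation/conditional-maximization scheme. Each cycle:

1. **E-step** — posterior group probabilities via log-sum-exp (no
   underflow; posteriors are exact zeros only when a component is at
   $-\infty$ relative to the rest).
2. **Mean curves** — each $\beta_k$ solves the posterior-weighted
   generalized least-squares normal equations exactly, with the group's
   current $\Sigma_k^{-1}$ as the within-subject weight.
3. **Covariance** — independence: the posterior-weighted mean squared
   residual. Exponential: a profile likelihood — $\sigma_k^2(\phi)$ has a
   closed form, and $\phi_k$ is found by a golden-section search on
   $\log\phi \in [\log 0.01, \log 100]$ (years). If the search does not
   improve on the current $\phi_k$, the current value is kept, so this
   step can never decrease the objective.
4. **Concomitant coefficients** — closed form for the intercept-only
   model ($\gamma_{k0} = \log(\bar w_k/\bar w_K)$); otherwise Newton
   iterations with step-halving on the posterior-weighted multinomial
   log-likelihood. Linear predictors are capped at $|\eta| \le 30$; a fit
   that ends on the cap warns about separation.

Because every step is a conditional maximization (or an explicit
no-decrease guard), the log-likelihood trace is monotone — this is asserted
by the test suite on every fit, to $10^{-10}$ per step.

Numerical choices: relative log-likelihood convergence tolerance $10^{-8}$,
iteration cap 500, variance floor $10^{-8}$ (hitting it warns and marks the
component degenerate), posterior ties broken toward the lowest group index.

**Multi-start.** Mixture likelihoods are multimodal. Twenty
initializations are used by default: one deterministic k-means partition of
visit-aligned centered vectors (missing visits imputed by the visit mean)
and nineteen random soft assignments. All starts run a short screening
phase (15 iterations by default) and the best is continued to convergence —
the standard screening strategy used by mixture packages, trading a small
risk of discarding a slow-burning start for a several-fold speedup.

**Label switching** is resolved by ordering groups by their fitted mean
curve value at the maximum observed age, descending: group 1 is always the
steepest riser and group K the flattest, which also fixes the reference
group of the concomitant model to the flat pattern.

## Model selection and classification

`select_model()` fits the covariate-free mixture for $K \in \{2,\dots,5\}$
under both covariance structures and minimizes
$\mathrm{BIC} = -2\ell + d\log n$. Two choices the data cannot make for us:

* $n$ is the number of **subjects**, the mixture's independent units, not
  the number of records.
* $d = K\,(\text{basis dim}) + K\,(1\text{ or }2) + (K-1)(1+p)$.

Children are classified into the group with the largest posterior
probability. As a calibration readout, `classify()` reports per group the
fraction of posterior probabilities strictly between 0.1 and 0.9 — small
fractions mean well-separated groups.

## Association analysis

After $K$ and the covariance structure are fixed, each exposure enters the
concomitant model (one exposure at a time, unadjusted and adjusted for the
confounder set) and the **whole mixture is re-estimated** — means,
covariances and $\gamma$ jointly — warm-started from the covariate-free
posteriors plus random restarts. Under the multinomial logit, the relative
risk ratio for group $j$ versus the reference under a $\delta$-unit
covariate increase is constant in $z$ and equals
$\exp(\delta\gamma_{j})$; with log10-transformed exposures, $\delta = 1$ is
a ten-fold concentration increase.

Wald intervals use standard errors from the inverse **observed information
of the full mixture likelihood** at the MLE, computed by central
differences (step $10^{-4}$ on each parameter's natural scale). This
propagates classification uncertainty into the intervals, unlike the
cheaper two-stage variant (`wald_ci(..., method = "two_stage")`), which
conditions on the fitted posteriors and uses only the multinomial block.
Which variant the original analysis used is not documented; the full-model
information is the default here because the model is re-estimated jointly.
Two-sided Wald p-values are reported without multiplicity correction.

## The synthetic cohort

The cohort this method was built for is restricted, so
`default_growth_scenario()` encodes a synthetic stand-in with the same
statistical skeleton, used by the tests, the analysis scripts and the
acceptance checks. Its defaults are fixed once:

* **Design**: 500 children (~250 per sex), visits at ages
  2, 3.5, 5, 7, 9; each visit independently missing with probability 0.04
  with a hard floor of 4 retained visits (the inclusion rule), matching
  per-visit attrition of a few percent.
* **Shapes** (centered scale): group 1 linear rise (slope 1.28 kg/m²/yr),
  group 2 flat then rising from age ~4.5 (slope 1.35), group 3 flat then
  rising from age ~6.5 (slope 1.45), group 4 flat — the four canonical
  patterns, with raw base levels 24.0/20.8/18.4/16.2 kg/m² so raw-scale
  summaries look like a real cohort.
* **Heterogeneity and noise**: Normal subject-level offsets
  (SD 1.5 kg/m²) — the level variation the centering removes — and
  independent within-subject noise (SD 0.6 kg/m²), a plausible scale for
  short-term BMI fluctuation around a smooth trajectory.
* **Covariates**: log10 serum exposures with the cohort's published
  geometric means and SDs (p,p'-DDE GM 1428, GSD 3.4 ng/g lipid, etc.),
  correlated through a shared factor (r ≈ 0.5–0.7); four confounders
  (years in the USA, maternal pre-pregnancy BMI, birth weight,
  breastfeeding duration) with realistic marginals; preterm and
  low-birth-weight flags derived from simulated gestational age and birth
  weight.
* **Membership model**: exposure log-odds per ten-fold increase of
  log(1.2)/log(3.6)/log(2.6) for groups 1–3 versus the flat reference,
  mild confounder effects, intercepts solved so marginal group
  proportions at the covariate means are ≈ 14/18/29/39% — the relative
  group sizes a cohort like this reports.

One seeded stream drives all draws in a fixed order (covariates, labels,
offsets, missingness, then noise subject by subject), so a seed fixes the
cohort bit-for-bit and subject order cannot influence content.

What the generator does *not* emulate: measurement error spikes, skewed
BMI distributions within group, informative (non-random) missingness,
age jitter around nominal visits, below-LOD exposure censoring (covariates
are drawn directly on the log10 scale), and any direct effect of
covariates on BMI level. Passing tests therefore demonstrate correctness
of the machinery under the model's own assumptions — not robustness to the
ways real cohort data violate them.

Problem sizes used by the checks (chosen as comfortable desk-scale
simulation sizes): selection studies at n = 250 per stratum over 10 seeds;
a 1-group null at n = 150; exposure-effect recovery at n = 800 with 25
replicates; oracle comparisons at n = 30.

## Numerical and degenerate-input behavior

* Subjects with a single visit carry no shape information (their centered
  vector is identically zero) and are dropped from centering with a
  warning.
* Tiny instances with only 3 distinct ages cannot support the default
  4-dimensional basis (the stacked design is rank-deficient); such
  analyses use `build_spline_basis(..., n_internal = 0)` (dimension 3).
  Rank deficiency in an M-step is reported as an error naming the group.
* A component whose residuals vanish hits the variance floor ($10^{-8}$)
  with a warning rather than producing an unbounded likelihood spike.
* Complete separation in the concomitant model is capped at
  $|\eta| \le 30$ with a warning instead of diverging.
* All-component underflow in the E-step cannot occur: computations stay
  in the log domain.

## Limitations

* **BIC under the null is mildly anti-conservative here.** In a 1-group
  null simulation (n = 150), BIC picked the smallest candidate K in 8 of
  10 replicates; in the other 2 it admitted one spurious extra group that
  captures a small, low-variance cluster. This traces directly to the
  working-covariance compromise: the true covariance of centered vectors
  has negative equicorrelation that neither working structure represents,
  so additional components can genuinely improve the working-model fit.
  Users should treat a BIC margin of a few points between adjacent K as
  ambiguous, and inspect group sizes and variances (a tiny group with a
  variance far below the bulk is a warning sign).
* The exponential range $\phi$ is weakly identified on 4–5 visits per
  subject; its search is bounded to [0.01, 100] years.
* Wald intervals rely on an interior optimum; fits flagged for separation
  or floored variances do not have trustworthy standard errors.
* RRRs are associations of membership with baseline covariates under the
  fitted model; no causal adjustment (weighting, g-methods) is attempted,
  and CIs are asymptotic, not bootstrap.

## Reproducibility

Every stochastic entry point takes an explicit integer seed;
`select_model()` derives one deterministic seed per grid cell,
`run_pipeline()` one per stage and stratum. Identical configuration and
inputs reproduce identical outputs, and the pipeline writes a manifest
(config hash, seed, package and R versions) alongside its tables. The
per-subject mean used in centering is stored, so the transformation is
exactly invertible.
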