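---
title: "Modelling plasma triglyceride excursions during oral lipid tolerance tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling plasma triglyceride excursions during oral lipid tolerance tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olttmod)
```

## The model

An oral lipid tolerance test (OLTT) challenges a subject with a defined
amount of dietary fat and follows the plasma triglyceride (TAG)
concentration over the next hours. `olttmod` implements a semi-mechanistic
PK/PD model of that excursion and of its suppression by an inhibitor of
DGAT1, the enzyme catalysing the final step of intestinal TAG synthesis.

The TAG side is an indirect-response turnover model with an exogenous
input. The challenge loads a gut depot with `A_TAG` mg of TAG after a lag
`Tlag_TAG`; the depot empties with first-order rate `ka_TAG`; plasma TAG
turns over around its baseline:

* `dA_TAG/dt = -ka_TAG * A_TAG`
* `EXOG_TAG = A_TAG / V_TAG`
* `dC_TAG/dt = R0 * kout + EXOG_TAG * ka_TAG * Inh(C) - kout * C_TAG`

The endogenous production rate is parameterized as `kin = R0 * kout` so
that the baseline `R0` — a directly observable quantity — is estimated
instead of `kin`, which materially improves numerical stability. Drug
effect enters as a saturable reduction of the exogenous input,

* `Inh(C) = 1 - C / (C + IC50)`,

driven by the free plasma concentration of the inhibitor. The inhibited
fraction of the depot outflow is malabsorbed — it leaves the system rather
than entering plasma later, which matches the mechanism (unesterified
lipid is not secreted as chylomicron TAG on the test's time scale).

Drug disposition is a one-compartment (rodent) or two-compartment (human)
linear model with first-order absorption, evaluated in closed form and
superposed over dosing events.

### Unit conventions

Three conventions matter when reading the default parameter sets
(`species_truth()`), which reproduce the published cross-species
population estimates:

* All PK parameters are on the **free-concentration scale**: the analysis
  is carried out entirely in free (unbound) concentrations, so `V` and
  `Cl` are apparent free-scale quantities and `pk_profile()` returns free
  concentrations directly. `free_concentration(total, fu)` converts
  total-concentration assay data on import (fu = 0.055 human, 0.03 rat,
  0.1 mouse). On a total-concentration reading, the rat dose range could
  produce at most a few percent inhibition at the published IC50, which is
  inconsistent with the reported effect sizes; the free-scale reading
  makes all three dose ranges straddle their IC50.
* Rodent doses are per kg body weight; correspondingly, rodent `V` and
  `Cl` are per-kg quantities. The mouse values (V = 13.14 L, Cl = 2.17
  L/h) are physically implausible as absolute quantities for a 25 g animal
  and consistent as per-kg free-scale values (total-scale equivalents
  1.31 L/kg and 0.22 L/h/kg). Human doses and volumes are absolute.
* The TAG side is absolute in every species: challenge masses in grams
  per subject and `V_TAG` in dL (mouse V_TAG = 0.012 dL is about the
  plasma volume of a mouse).

Dietary challenges convert to grams of TAG as: meal fat energy / 9 kcal
per gram (`meal_tag_dose()`); oil gavages as volume x body weight x oil
fraction x density (`oil_tag_dose()`; corn oil 0.9 g/mL, soybean oil
0.917 g/mL), assuming complete absorption in the absence of drug. The
drug's molecular weight is not part of the published parameterization;
dose conversion to µmol uses a configurable value (`mw`, default 420
g/mol) that is a documented assumption of this package — any consistent
choice rescales `V`, `Cl` and leaves the model's behaviour unchanged.

## The hierarchical layer

Inter-individual variability is log-normal on the parameters listed per
species in `species_truth()$omega_cv` (exactly the parameters for which
IIV was estimable in each species). IIV magnitudes quoted as %CV are
interpreted as log-normal coefficients of variation, `omega =
sqrt(log(1 + (CV/100)^2))`; because some software reports `100 * omega`
instead, both conventions are supported (`iiv_convention`). Residual error
is proportional for both observation channels; the TAG magnitudes are the
published ones (0.192 human, 0.198 mouse, 0.3 rat) and the PK proportional
SD defaults to 0.15 as a package assumption (the source analysis does not
state one).

Human covariate models follow standard practice where the published
functional forms are not available: allometric body-weight scaling of `Cl`
(exponent 0.75) and `V` (1.0) referenced to 70 kg, fixed during
estimation; and a power model of BMI on `R0` referenced to 25 kg/m²,
estimated in the human fit. The synthetic-study generator uses exponent
1.0 as its truth — baseline TAG proportional to BMI — a one-time choice of
plausible effect size, since only the covariate's significance, not its
magnitude, is reported.

## Estimation

The marginal likelihood integrates the random effects out by a Laplace
approximation around per-subject empirical-Bayes modes. The objective is
implemented as a TMB C++ template, so inner modes, the log-determinant
correction and exact gradients come from automatic differentiation;
`fit_sequential()` (PK first, then TAG with exposure fixed — the study
templates carry no PK random effects, so stage 1 is a pooled fit) provides
the starting values for `fit_simultaneous()`, the joint fit of all fixed
effects, IIV SDs and residual SDs on the log scale. This mirrors the
original sequential-then-simultaneous protocol while replacing its
FOCE-ELS/QRPEM machinery with a Laplace approximation; objective-function
values are therefore not comparable across engines, and the package's
validation relies on parameter recovery rather than OFV equality.

Numerical choices that required care:

* **Semi-analytic TAG likelihood.** Because the TAG equation is linear
  given the inhibition input, each challenge contributes the convolution
  `(ka_TAG m / V_TAG) * int_0^{t-L} exp(-kout (t-L-u)) exp(-ka_TAG u)
  Inh(L+u) du` on top of the steady-state baseline. The likelihood
  evaluates it by composite Simpson quadrature with `n_quad = 32` panels,
  which agrees with the reference integrator to ~1e-6 relative at the
  default designs — three orders of magnitude below the residual error.
  Challenges that cannot see drug (placebo subjects; baseline meal
  occasions completed long before the first dose) use the exact
  double-exponential solution instead.
* **Smoothed lag onset.** A hard absorption lag makes the likelihood
  non-differentiable whenever a subject's depot-onset time crosses an
  observation time; gradient-based optimization then stalls on needle-like
  creases. The likelihood therefore smooths the onset with a softplus of
  width 0.01 h (~36 s, far below the 30-min sampling resolution); the
  simulator keeps the hard lag, and the induced prediction differences are
  orders of magnitude below residual noise.
* **Stability.** Rate-constant differences near zero switch to series
  expansions; exponent arguments are clamped so no intermediate can
  overflow (an Inf in an unselected conditional branch poisons
  reverse-mode derivatives); optimization runs on log-transformed
  parameters within generous bounds (`log omega` in [-8, 3]); non-finite
  objective evaluations are penalized and counted, never silent.
* **Initialization and restarts.** The published estimates ship as
  defaults and are good starting values for OLTT-shaped data. Because the
  simultaneous fit starts from the sequential solution, multi-start
  optimization is rarely needed and is off by default (`n_starts` in
  `fit_control()` enables jittered restarts). Convergence requires either
  a clean optimizer return or a small final gradient; "false convergence"
  returns at a genuinely small gradient are accepted, a well-known
  behaviour of `nlminb` on Laplace objectives.

Standard errors come from the numerical Hessian of the marginal -2
log-likelihood at the optimum; on the log scale `100 * SE(log theta)` is
directly the %CV of the estimate. Directions in which the Hessian is not
positive definite are reported `NA`. Nested models are compared by
likelihood ratio with the chi-squared P = 0.001 criterion (10.83 for one
degree of freedom).

## The synthetic-study generator

No individual-level OLTT data are distributable with the package, so every
stage is exercised against synthetic studies that reproduce the four
published designs (`make_design()`): the human single-ascending-dose study
(10 cohorts of 6 active + 2 placebo, 1-60 mg, 1100 kcal mixed meal with
60% or 45% fat energy served as a pre-dose baseline occasion and again 4 h
post dose), the multiple-ascending-dose study (42 active across 1-20
mg/day for 7 days + 20 placebo, 45% fat meal 1 h post dose), the rat study
(53 animals: vehicle 11, 0.1/0.3/3 mg/kg x 12, 6 naive controls; corn oil
5 mL/kg at 2 h; TAG at 2-11 h) and the mouse study (41 animals: vehicle 8,
0.1/1/3 mg/kg x 11; 20% soybean emulsion 10 mL/kg at 0.5 h). Rodent
designs reproduce the sparse-PK structure: 3 animals per active group are
serially bled for PK and contribute no TAG samples, so the estimator is
exercised under realistic sparsity.

Details the sources do not print were fixed once as documented
assumptions: human TAG sampling at {0, 0.5, 1, 1.5, 2, 3, 4, 6, 8} h post
meal and rich PK sampling at {0.25-12} h post dose; human body weight
log-normal (median 80 kg, CV 15%) and BMI normal (27 +/- 3, truncated to
18-40 kg/m²); rodent body weights fixed at 0.23 / 0.025 kg; the
single-ascending-dose timeline (baseline meal at 0 h, dose at 24 h, test
meal at 28 h) follows the study's figure annotations.

What the generator deliberately does not emulate — and hence what passing
recovery tests cannot certify about real data: early TAG peaks from
previous meals, meal-to-meal carryover, below-limit-of-quantification
handling, dropout, correlated random effects, and any drug effect on
gastric emptying. The generator is a faithful simulator *of the model*
under the published designs; recovery results certify the estimation
machinery, not the model's biological adequacy.

## Recovery behaviour and known limitations

With the published values as simulation truth, the full rodent designs
and a reduced human design (6 dose levels spanning 1-60 mg, 48 subjects —
the scale used throughout the package's acceptance checks to keep each
replicate well under 5 minutes on one CPU) recover the structural
parameters well: replicate medians of the baseline and the absorption lag
land within a few percent of truth, the turnover rate within ~15%, and
clearance and the rodent potencies within the estimator's replicate
scatter. Caveats worth knowing:

* The human IC50 carries a 223% CV random effect (log-scale SD ~1.34).
  With 36 active subjects per replicate the population-IC50 estimator is
  correspondingly noisy (replicate SD ~25-30% on the log scale) and
  right-skewed; replicate medians can sit 10-25% from truth even though
  the estimator is consistent (a 240-subject fit recovers both IC50 and
  its 223% IIV essentially exactly). This is a property of the reduced
  design, not of the code path.
* `kout` and `V_TAG` are partially confounded when sampling ends while
  the excursion is still elevated (the mouse design); occasional
  replicates find a correlated ridge solution, or the classical
  rate-exchange ("flip-flop") mode in which `ka_TAG` and `kout` swap
  roles with a compensating `V_TAG`. The incremental AUC these
  parameters control remains stable, as does IC50.
* Optimizer endpoints on the Laplace surface can sit on creases where
  gradient magnitudes are uninformative; convergence is therefore
  declared on a clean return code, a small gradient, or
  restart-certified stationarity (no progress from a re-started
  optimization), with the final gradient kept on record in the fit
  object.

## Diagnostics

`vpc()` simulates replicate studies (1000 by default) from a parameter
set and overlays observed data on pointwise medians and 95% prediction
intervals of the individual profiles (IIV and residual error included),
stratified by arm; `gof_table()` produces population and
empirical-Bayes individual predictions and proportional-error weighted
residuals `(obs - IPRED)/(sigma IPRED)` — a deliberate, documented
simplification of conditional weighted residuals, adequate here because
model evaluation rests on simulation-based calibration rather than on
residual minutiae. `plot_vpc()` and `plot_gof()` render one panel per
arm.

## Pipeline

`cmd_simulate()`, `cmd_fit()`, `cmd_vpc()` and `cmd_recover()` wrap the
stages behind YAML/list configs (every source of randomness flows from the
config seed; identical configs give identical outputs), and
`inst/cli/olttmod` exposes them as a thin command-line entry point. A
typical recovery study:

```{r, eval = FALSE}
r <- cmd_recover(list(template = "rat", n_seeds = 10, seed = 1,
                      out = "rat-recovery"))
r$report
```
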