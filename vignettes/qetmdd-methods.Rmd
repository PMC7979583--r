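---
title: "A quasi-equilibrium multiple-target TMDD model for a VAP-1 inhibitor: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quasi-equilibrium multiple-target TMDD model for a VAP-1 inhibitor: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qetmdd)
```

## The model

ASP8232 is an oral small-molecule inhibitor of vascular adhesion protein-1
(VAP-1), an amine oxidase that circulates in a soluble form (sVAP-1) and
sits membrane-bound (mVAP-1) in tissues.  Because the drug binds its target
with high affinity and the target is abundant, binding feeds back on the
drug's own disposition: this is target-mediated drug disposition (TMDD).
`qetmdd` implements the population PK-PD model for this compound as a
simulation and estimation toolbox.

The structural model is a three-compartment disposition system with
first-order absorption through one transit compartment and a lag time.
The state holds total drug amounts (free plus bound, nmol): depot `A1`,
transit `At`, central `A2` (volume `v2`), and two peripheral compartments
`A3` (volume `v3 = v2`) and `A4` (volume `v4`).  Target is present as
soluble plus membrane-bound pools in the central compartment (total
`tvap1c`) and membrane-bound pools in each peripheral compartment
(`mvap1p1`, `mvap1p2`), all parameterised as fixed multiples of the
central soluble concentration `svap1c`.

Binding is treated under the quasi-equilibrium approximation: association
and dissociation are fast compared with every other process, so at any
instant the free/bound split is algebraic, governed by a single
dissociation constant `kd` shared by all binding sites.  For a species
with total concentration $C$ facing a binding partner with total
concentration $T$, the free concentration is the positive root of

$$C_{free}^2 + (T + K_D - C)\,C_{free} - K_D C = 0,$$

and the free *fraction* $\phi = C_{free}/C$.  Only free drug distributes
and is eliminated, so every rate constant in the ODE right-hand side is
weighted by the free fraction evaluated in its source compartment; target
turnover and elimination of the drug-target complex are assumed
negligible, so the target pools are constant.

Three observation equations map the state to what the assays measure, on
the natural-log scale: total measured drug (free drug plus the share of
complex bound to *soluble* target -- drug bound to membrane target is not
in plasma), total soluble target (constant under the no-turnover
assumption), and plasma enzymatic activity, a power function
`sl * (free sVAP-1)^pow` of the free soluble target concentration.

Covariates enter as in the final published model: baseline eGFR acts on
clearance through a sigmoid-Emax ("on/off", hill coefficient fixed at 10)
relationship and on relative bioavailability through a power term;
females have 12.5% higher target concentrations in every pool.  Log-normal
inter-individual variability applies to clearance, the soluble target
concentration and the activity slope, with a full 3x3 covariance block;
residual error is additive on the log scale per observation type, with an
estimated SD multiplier for drug and activity observations from the
phase-2 studies.

## Parameters and units

All doses are converted to nmol with the free-base molecular weight
(444 g/mol); concentrations are modelled in nM and drug concentrations
reported in ng/mL (`1 nM = 0.444 ng/mL`).  The defaults of
`tmdd_params()` and `tmdd_variability()` are the published estimates; a
YAML mirror ships in `inst/extdata/asp8232_params.yaml`.

One constant is a genuine modelling choice rather than a published value:
the reference eGFR normalising the bioavailability power term,
`egfr_ref_f1`.  We default it to 44 mL/min/1.73m^2, the DKD-study median.
With that convention the typical DKD subject (male, eGFR 44) has a
relative bioavailability of exactly 1, and the package reproduces the
published typical-subject steady-state exposure table to within about 2%
at 10-40 mg; normalising at the pooled-data median (64) instead leaves a
systematic 8-9% offset in those reference simulations while changing no
ratio-type result (the exposure ratio between eGFR 20 and 110, the
dose-normalised exposure curve and the inhibition results are invariant
to the reference).  The parameter remains configurable for sensitivity
analyses.

## Numerical choices

* **Integration.** The right-hand side is compiled C, driven by
  `deSolve::lsoda` with doses injected as depot events at their nominal
  time plus the absorption lag.  Reference simulations use
  `rtol = 1e-8`, `atol = 1e-10` nmol: the free-fraction nonlinearity
  produces sharp gradients when concentrations cross `kd` at low doses.
  The estimation path relaxes to `rtol = 1e-6`, `atol = 1e-8`
  (configurable), which changes the objective well below the precision of
  any estimate.
* **Free fractions.** The closed-form quadratic root is evaluated in a
  conjugate arrangement that avoids catastrophic cancellation when total
  drug is far below target plus `kd`, and the indeterminate 0/0 limits at
  zero totals are taken analytically (`kd / (kd + T)` for the drug side).
* **Steady-state metrics.** The final dosing interval is sampled at
  0.1 h and integrated by the trapezoid rule; at that resolution the AUC
  error against the analytic linear-limit value is below 0.1%.  Troughs
  are sampled immediately before each daily dose; the time to steady
  state is the first daily trough reaching 97% of the week-52 trough, and
  the apparent half-life is that time divided by 5 (so both are
  quantised to whole days).  The 52-week horizon (364 days) guarantees
  steady state at every dose in the 0.1-40 mg range.
* **Simulation range.** Doses outside 0.1-200 mg warn rather than fail:
  the binding parameters were characterised inside that range, and
  neglected target turnover may bias extrapolations beyond it.

## Estimation

Individual (empirical-Bayes) random effects are MAP estimates: the
penalised deviance `individual_neg2ll + eta' Omega^-1 eta` is minimised
by a damped Gauss-Newton iteration in which two Jacobian columns come
from forward-difference ODE solves and the activity-slope column is
exact; `map_etas()` multistarts from the prior mode and +/-0.5 on each
axis.  Inside the population fit the iteration runs warm-started with
rank-one (secant) Jacobian updates between exact refreshes.

The population objective is the Laplace approximation of -2 log marginal
likelihood,

$$\mathrm{OFV} = \sum_i \Big[\; \mathrm{neg2ll}_i(\hat\eta_i)
  + \hat\eta_i^\top \Omega^{-1} \hat\eta_i + \log|\Omega|
  + \log|H_i| \;\Big],$$

with $H_i$ the Gauss-Newton curvature of the penalised individual
objective at the MAP etas -- the same curvature shortcut classical
FOCE-type estimators take.  The outer step over the free fixed effects is
a profiled Gauss-Newton step: prediction sensitivities to the fixed
effects are finite-differenced at the MAP etas and the per-subject random
effects are profiled out through the Schur complement of the joint
Gauss-Newton system, so each step anticipates how the etas re-adjust.
Between cycles, the covariance block is updated by the EM-type
closed form $\Omega \leftarrow N^{-1}\sum_i (\hat\eta_i\hat\eta_i^\top +
H_i^{-1})$, and optionally the residual variances by the analogous
residual update.  The theta-dependence of the $\log|H_i|$ term is
neglected in the search direction (it is always included in the reported
OFV); positive parameters are optimised on the log scale.

Because the inner problems are re-converged to a step tolerance of
`1e-4`, the OFV is reproducible to roughly `1e-4` relative -- OFV
differences used by the covariate search (6.63 and 10.8 points) are three
orders of magnitude above that.

`stepwise_covariates()` reproduces the published selection procedure:
univariate screen ranked by OFV drop, forward inclusion at 6.63 points
(chi-square, 1 df, p < 0.01), backward elimination at 10.8 points
(p < 0.001).  Outliers are flagged at conditional weighted residuals
strictly beyond +/-3, computed at the MAP etas as the log-scale residual
over its residual SD; this MAP-conditional standardisation approximates
the FOCE-based CWRES of classical workflows.  Flagged rows (and
below-LLOQ drug records) are excluded by masks, never deleted.

## The synthetic cohort generator

No clinical data are distributed, so `sample_covariates()`,
`sample_etas()` and `generate_dataset()` stand in for the study datasets.
The `"ALBUM"` population preset emulates the phase-2 DKD study: 77.5%
male; baseline eGFR from a truncated normal with mean 44 and SD 11.1
mL/min/1.73m^2 on [22.1, 71.5].  The mean equals the published median and
the SD is reconstructed from the published 5th/95th percentiles under
normality, `(63.4 - 26.9) / (2 * 1.645)`; the truncation bounds are the
published minimum and maximum.  Body weight is sampled log-normally
around the study median as a pass-through covariate (the final model has
no weight effect) and travels in the `WT` column.  Sampling-design
presets encode the phase-2 week grid (drug at weeks 2-36; target
concentration and activity from baseline) and a rich phase-1 style
schedule; arbitrary schedules are accepted.

Datasets are NONMEM-style tables (`ID, TIME, AMT, EVID, CMT, DV, MDV,
LLOQFLAG, SEX, EGFR, PHASE, WT`) with log-scale observations typed by
compartment code (2 drug, 3 soluble target, 4 activity).  Drug records
simulated below the 0.1 ng/mL assay limit are flagged rather than
dropped, and estimation ignores them by default -- the studies reported
no activity values below quantification, and flagging keeps the
record count an invariant of the design.  The phase-2 residual factor
multiplies the residual *SD* (the pharmacometric convention), not the
variance.

What the generator deliberately does not emulate: dropout and
compliance, placebo-arm activity drift over time (noted but unexplained
in the source studies), assay-specific censoring mechanisms, and any
weight effect.  Passing tests therefore demonstrate internal consistency
of the machinery under the model's own assumptions, not robustness to
those real-data features.

## Model evaluation

`vpc()` re-simulates a dataset at its own design (same subjects, doses,
covariates, scheduled times) with fresh etas and residuals, the
conventional 100 replicates by default, and reports per type and
scheduled time the observed 5th/50th/95th percentiles next to the
simulated median of each percentile and the 90% prediction interval of
the simulated median.  `concentration_effect_curve()` traces predicted
inhibition against measured plasma concentration (inverting the
observation equation by monotone root finding) and locates the 50%
inhibition concentration.  For model-predicted inhibition the reference
is the drug-free model activity; for observed data the convention is the
median of the subject's pre-dose activity observations, so observed
inhibition can be negative through measurement error.

## Problem sizes

The packaged reference computations use: typical-subject 52-week
once-daily simulations (364 doses, dense final day) for the exposure
table and its ratios; 1000 virtual DKD patients for the population
dose-response summaries; 120-subject phase-2-sized datasets, three
replicates, for the parameter-recovery checks; 1e5 draws for
distributional checks of the random-effect block.  These sizes put every
Monte-Carlo error well inside the tolerances they are compared against
while keeping the full suite comfortably runnable on a laptop.

## Known limitations

* No target turnover or complex elimination: faithful to the published
  model, but a known source of bias if extrapolated beyond the studied
  dose range.
* The Laplace/Gauss-Newton objective is not numerically identical to any
  specific NONMEM estimation method; agreement is at the level of
  parameter recovery, not objective-function values.
* Confidence intervals from the observed-information inverse are not
  implemented; the estimation surface is point estimation, shrinkage and
  likelihood-ratio comparisons.
* The model predicts inhibition tending to zero at vanishing
  concentrations; the source studies observed a residual ~20% apparent
  inhibition at very low concentrations that the model intentionally
  does not reproduce.

## A worked example

```{r example, eval = FALSE}
# typical DKD subject, 10 mg once daily for a year
prof <- simulate_qd(10, weeks = 52)
secondary_params(prof)

# concentration-effect relationship and its midpoint
curve <- concentration_effect_curve()
attr(curve, "ic50_ng_mL")

# a synthetic phase-2 study and a refit of four parameters
cohort <- sample_covariates(population_spec("ALBUM", n = 120), seed = 1)
dat <- generate_dataset(cohort, sampling_design("ALBUM"), seed = 2)
fit <- fit_population(dat, params = tmdd_params(cl = 22),
                      free = c("cl", "svap1c", "sl", "pow"))
tidy(fit)
glance(fit)
```
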