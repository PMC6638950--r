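---
title: "Modelling growth retardation with interval-censored multi-state models, multiple imputation and a Heckman-corrected GEE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling growth retardation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(growthmsm)
```

## The problem

In longitudinal cohorts of young children — the motivating setting is
pediatric HIV care in sub-Saharan Africa — growth retardation is episodic:
children fall below and recover above the malnutrition threshold repeatedly,
death competes with (and is accelerated by) malnutrition, nutritional state
is only seen at scheduled visits, and attendance itself depends on how the
child is doing. Each of these features breaks a naive time-to-first-event
analysis. `growthmsm` implements the full chain of methods this setting
requires: WHO growth-standard scoring, a three-state panel Markov model,
chained-equation multiple imputation with likelihood-ratio pooling, and a
two-stage selection-model correction for informative missingness of the
growth outcome itself.

## Anthropometric scoring

A measurement `y` (kg or cm) is scored against reference parameters
L (Box–Cox power), M (median) and S (coefficient of variation) as

$$ z = \frac{(y/M)^L - 1}{L\,S}, \qquad z = \frac{\log(y/M)}{S} \ \text{as}\ L \to 0 . $$

The branch switch sits at `|L| <= 1e-8`, where the two forms agree to
O(L·z²·S) — far below measurement precision. Age-keyed indices (WAZ, LAZ)
use completed months (floor); weight-for-length is keyed on recumbent length
rounded to the table's 1 mm grid. For the weight-based indices the WHO
restricted-tail convention replaces `|z| > 3` with a linear extrapolation in
measurement space based on the ±2 and ±3 SD reference bounds, so a
biologically absurd weight cannot produce an astronomically large score;
length-for-age is left untouched. We adopt the restricted form as the
default because the reference software used in the field applies it;
`compute_zscores(..., restrict = FALSE)` disables it.

Classification into the panel state space is strict at the threshold:
`z < -2` is malnourished, `z = -2` exactly is healthy, and death dominates
any score. Scores with `|z| > 6` are flagged implausible but retained —
exclusion is an analysis decision, not a scoring decision.

The package ships a *synthetic* LMS reference (`synthetic_lms_table()`):
smooth, internally consistent L/M/S curves with bounds derived by the
inverse transform, adequate for tests and examples and clearly unsuitable
for clinical use. Real WHO CSV exports with the same schema are read by
`read_lms_table()`, which checks bound ordering and the self-consistency of
the bounds with (L, M, S) to a relative 1e-6.

## The three-state panel model

States are 1 = healthy, 2 = malnourished, 3 = dead (absorbing), with
transitions 1→2, 1→3, 2→1, 2→3. Transition intensities are
piecewise-constant on age bands (0,6], (6,12], (12,60] months — the bands on
which the motivating analyses report intensities — and covariates act
proportionally on each transition:

$$ q_{rs}(x, \text{band}) = q^0_{rs,\text{band}} \exp(\beta_{rs}' x). $$

Covariate effects are shared across bands (one hazard ratio per covariate
per transition); band-specific effects would be estimable in principle but
the reported analyses print a single adjusted hazard ratio per covariate,
and the shared form is the identifiable default at cohort sizes of a few
hundred children. Age-band contrasts themselves are read off the baseline
intensities as ratios between bands rather than treated as covariates.

The likelihood is the standard mixed panel form. For a pair of observations
(state r at t₁, state s at t₂) the contribution is the (r,s) entry of the
interval transition matrix — an ordered product of matrix exponentials over
the maximal sub-intervals on which the band is constant, with
time-dependent covariates held at their interval-start values (the usual
panel-data approximation). For an exactly observed death at t₂ the
contribution is $\sum_{k \in \{1,2\}} P_{rk}(t_1, t_2)\, q_{k3}(t_2)$: the
live state just before death is unknown and is summed out. Children enter
the likelihood at their first non-missing state (delayed entry by
conditioning); visits with a missing state are skipped and the interval
spans them.

Because the death row is absorbing, the 3×3 matrix exponential reduces to
the exponential of the 2×2 live-state block, which has provably real
eigenvalues (the discriminant is a sum of squares and a product of
non-negative rates); the package evaluates it in closed form, with the
nilpotent expansion at (near-)coincident eigenvalues, and the death column
by complement. The user-facing `transition_probability()` uses
uniformization instead, and the test suite cross-checks both against
`Matrix::expm` and a Runge–Kutta integration of the forward equations.

**Fitting.** Likelihood evaluations aggregate identical
(t₁, t₂, r, s, covariate-pattern) contributions, so one evaluation costs a
few dozen closed-form exponentials regardless of cohort size. Maximisation
is quasi-Newton (L-BFGS-B) with numerical derivatives from crude
occurrence/exposure starting rates floored at 1e-4 per month, covariate
effects started at zero. Log-intensities are box-constrained to
[log 1e-6, log 5]: an intensity at the lower bound is indistinguishable from
a structural zero and is reported as unidentified (NA variance) rather than
producing a singular covariance for the whole fit. Transitions never
directly observed in the data are fixed at intensity zero and excluded.
The covariance is the inverse of the numerically differentiated observed
information on the identified block; intensity intervals are formed on the
log scale, `1000\,q\,\exp(\pm 1.96\,\widehat{se}(\log q))`, which keeps
bounds positive and reproduces the asymmetric intervals typical of sparse
transitions.

## Multiple imputation and pooled tests

Covariate missingness (around 10% per variable in the motivating design) is
handled by chained equations: Bayesian linear regression draws for
continuous variables (predictive mean matching with 5 donors as an option),
logistic draws for binary, multinomial draws for factors, 10 iterations and
10 imputations by default, each chain independently seeded. Anthropometric
outcomes are never imputed — their missingness is the subject of the
selection model instead.

Coefficients are pooled by Rubin's rules on the estimation scale
(log-intensities and β, not hazard ratios, since the rules assume
approximate normality): `T = W + (1 + 1/m) B` with the standard small-sample
degrees of freedom. Model comparison across imputations uses the Meng–Rubin
pooled likelihood ratio: per-imputation LR statistics at their own MLEs give
`d̄_m`; parameters are pooled by averaging and the LR statistic is
re-evaluated at the pooled parameters on each completed dataset to give
`d̄_L`; then `r_L = \frac{m+1}{k(m-1)}(d̄_m - d̄_L)` (clipped at zero, with
a message, when sampling noise makes it negative) and
`D3 = d̄_L / (k(1+r_L))` referred to an F distribution with the published
denominator degrees of freedom. This construction requires every fit object
to be re-evaluable at arbitrary parameter values on its own data;
`fit_msm()` returns a closure for exactly this purpose, and the same
contract is honoured by any model object carrying `estimate`, `loglik` and
`loglik_fun`.

## Informative missingness of the outcome

Attendance is worse for children doing worse, so the observed z-scores are
a selected sample. The package implements the two-stage correction for
repeated measures: stage 1 is a probit GEE for the indicator "z observed at
this scheduled visit" over all scheduled pre-death visits; the inverse
Mills ratio λ = φ(η̂)/Φ(η̂) at each observed record's stage-1 linear
predictor is appended to the stage-2 identity-link GEE for the marginal z
trajectory (age entering as age + age², age in years). λ is evaluated as
`exp(log φ − log Φ)` so that deeply negative predictors approach the
asymptote λ ≈ −η without overflow. Because λ is a generated regressor,
model-based standard errors for the corrected model are invalid; inference
comes from a cluster bootstrap (children resampled with replacement, both
stages re-run per replicate, percentile intervals, two-sided p as twice the
smaller tail fraction around zero; 500 replicates by default).

Both GEE solvers are iterated weighted least squares with a moment update
of the exchangeable correlation from standardized residuals and a sandwich
covariance clustered on the child; exchangeable is the default working
correlation in both stages. Identification of the selection term rests
partly on an exclusion restriction — at least one stage-1 covariate absent
from stage 2. The package warns when none is present, since λ is then
nearly collinear with the outcome design and the correction becomes
erratic; in the synthetic cohorts the clinic site plays this role
(affecting attendance but not growth).

## What the synthetic generator does and does not emulate

`cohort_config()` defaults encode the study conditions: four groups of
sizes 69/141/205/196 (HI, HIL, HEU, HUU); 3-monthly visits to 24 months
then 6-monthly to 60 for infected children, 6-monthly for uninfected;
baseline onset intensities 37.2/11.6/6.8 per 1000 person-months across the
three bands, healthy→death 9.6/20.1/0.3, malnourished→death 35.3/84.0/6.0;
group hazard ratios 3.3/4.3/0.7 (HI/HIL/HUU vs HEU) on onset. Recovery
intensities are not reported in the motivating analyses; we fix them once
at 80/60/40 per 1000 person-months — recovery faster than onset and
slowing with age, consistent with the recovered-by-next-visit patterns such
cohorts show. Death times are exact, all other states panel-observed.

The growth model behind `trajectory_first` cohorts is a quadratic in age
(years) with coefficients 0.84 and −0.16 — the scale of the fitted marginal
age profile — a child random intercept (SD 0.9) and residual SD 0.7, plus
group offsets (−0.3, −0.6, +0.27 for HI/HIL/HUU). MNAR dropout is a probit
on the current (possibly unobserved) z with slope −0.7; the intercept −0.5
makes roughly a third of scheduled visits unobserved, the scale seen in the
motivating cohort; the LH clinic shifts the missingness probit by +0.6,
providing the exclusion restriction. Under these defaults the observed-cell
mean z is biased upward, and — importantly — panel-observation times in
`state_first` mode become informative, so multi-state estimates under the
MNAR default are *deliberately* biased; parameter-recovery experiments use
MCAR (or no) dropout, which is the regime where the panel likelihood's
assumptions hold.

Covariates are simulated with marginal frequencies on the scale of the
motivating cohort's baseline table (sex, site, SGAG, birth size,
hospitalization, household water/electricity, maternal education and
occupation, marital status; time-varying chronic pathology, diarrhea, low
CD4, anemia, systemic signs). What the generator does **not** emulate:
measurement error in anthropometry, seasonality, within-child
autocorrelated residuals beyond the random intercept, informative covariate
missingness (covariates are MAR given group and site), or death depending
on z beyond the two-state distinction. Passing recovery tests on these
cohorts therefore demonstrates correctness of the estimators under their
stated assumptions, not robustness to every real-data pathology.

Per-child random streams are derived from the configuration seed, so
enlarging or subsetting a cohort leaves the retained children's data
byte-identical.

## Validation design and problem sizes

The suite validates by parameter recovery and oracle agreement, at sizes
chosen to give informative Monte-Carlo precision on a single CPU:

* panel likelihood vs an independently coded brute-force evaluation on a
  10-child panel at 20 random parameter draws (agreement to 1e-8);
* 95% Wald coverage of all 12 log-intensities over 300 replicate fits of
  2000-child cohorts, required to lie in [90%, 98%] per parameter (the
  sparse band-(0,6] cells make small-block coverage estimates noisy, so the
  experiment is sized above the minimum that would detect gross
  miscalibration);
* Heckman bias reduction over 200 replicate 600-child MNAR cohorts,
  comparing absolute median bias of the corrected vs naive group effect.
  The HIL-vs-HEU contrast is the pre-declared comparison: it carries the
  largest true offset, hence the strongest selection differential and the
  clearest correction target. These replicated experiments run the
  two-stage fit without the bootstrap — bias is a property of the point
  estimates, and the bootstrap is exercised at full size in its own tests;
* type-I calibration of the pooled LRT over 120 replications of a
  null-effect, MAR-missingness design, judged against an exact binomial
  99.5% band around the nominal 5%;
* smaller analytic identities (Rubin arithmetic, Meng–Rubin reductions,
  inverse-Mills values, GEE collapse to OLS/probit-ML) asserted exactly.

The replicated experiments are smaller than the corresponding production
recommendations (500 bootstrap replicates, 10 imputations); the methods are
identical, only replicate counts differ, and acceptance bands are computed
for the counts actually run.

## Numerical choices and degenerate inputs

* L ≈ 0 branch at 1e-8; LMS bound self-consistency tolerance 1e-6.
* Uniformization truncates the Poisson series at a 1e-17 tail; the
  closed-form 2×2 exponential switches to the nilpotent expansion when the
  eigenvalue gap is below 1e-9 relative to the trace.
* A zero-probability observed transition yields `-Inf` log-likelihood with
  a diagnostic naming the offending pair — never an exception — so the
  optimizer can retreat.
* Exchangeable α is clipped inside the valid range
  (−1/(max cluster − 1), 1); a singular working covariance falls back to
  independence with a warning.
* Perfect separation in a logistic imputation conditional is
  ridge-stabilised (λ raised to 1e-2) with a warning.
* Bootstrap replicates that fail are dropped and counted; more than 5%
  failures aborts.
* `r_L < 0` in Meng–Rubin pooling is clipped to 0 with a message; the
  F reference then degenerates to χ²/k.
* Ties at band boundaries: bands are half-open (lo, hi], and the death
  intensity at an exact death time uses the band containing that time.

## Known limitations

Hidden-Markov misclassification of the malnutrition state, semi-Markov
sojourn distributions, frailty terms, and a joint model for the three
indices are out of scope. The multi-state arm assumes non-informative
observation times; under the generator's MNAR default this is violated by
construction, and the package's answer to it is the Heckman arm for the
marginal trajectory, not a joint selection-multistate likelihood. The
synthetic LMS table is for testing only. Serialized fits restore summaries
but not the re-evaluation closure, so Meng–Rubin pooling must happen in the
fitting session.
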