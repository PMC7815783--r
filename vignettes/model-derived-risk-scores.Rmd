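---
title: "Deriving diabetes risk scores from a simulated population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving diabetes risk scores from a simulated population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diabrisk)
```

## Overview

`diabrisk` chains four stages that are usually performed on survey data
onto a simulated population instead:

1. **Simulate** an age-structured compartmental population of type 2
   diabetes (T2DM) and its behavioural risk factors forward in time.
2. **Sample** individuals from the simulated population at a chosen year,
   as if running a cross-sectional survey.
3. **Derive** an integer points score from a multivariable logistic
   regression on the sample.
4. **Evaluate** the score's diagnostic performance and the testing
   programme it implies.

This vignette explains the model and estimator, the parameters that matter,
the numerical choices, what the synthetic-data generator does and does not
emulate, and the known limitations.

## The compartmental model

The population is stratified by sex (2), five-year age band (20 bands, 0–4
through 95–99, band $k$ covering $[5k, 5k+5)$), the $2^3 = 8$ combinations
of obesity, daily smoking and physical inactivity, and diabetes status (2):
640 compartments. Occupancies are continuous person-masses, not integer
persons.

Dynamics are standard first-order compartmental flows, integrated by
forward Euler (difference equations):

* **entry** of new persons into band 0, factor-free and non-diabetic, at
  `entry_rate` persons/year by sex;
* **aging** between adjacent bands at a constant per-capita rate
  (default $1/5$ per year, i.e. exponential band residence with mean five
  years; the terminal band does not age out);
* **mortality** at per-capita rates that may depend on sex, band and
  diabetes status (neutral — equal across disease states — by default);
* **factor onset and reversal**, one factor per flow term, at per-capita
  rates per factor, sex and band;
* **diabetes incidence** from every non-diabetic compartment at hazard
  $$\lambda(\text{sex}, k, \text{profile}) =
    \lambda_0(\text{sex}, k) \prod_f RR_f^{\,I(\text{profile carries } f)},$$
  i.e. relative risks of co-occurring factors compose multiplicatively —
  the standard hazard-ratio composition, chosen because overlap-specific
  risks are rarely available. Diabetes is absorbing: no remission flow, and
  diagnosis status is not modelled.

**Units and defaults.** All rates are per-capita per year; `rr` are unitless
relative risks (> 0, default 1 = neutral); `entry_rate` is persons/year.
The default step is `dt = 0.1` year.

**Numerical choices.** Forward Euler is first-order: the single-cohort
constant-hazard test reproduces $1 - e^{-\lambda t}$ with error that
shrinks linearly in `dt` (verified in the tests). A step is rejected when
`dt` times any compartment's total per-capita outflow exceeds 1 — the exact
condition under which Euler occupancies could go negative — so
non-negativity and (in closed populations) exact mass conservation hold by
construction. `dt` is capped at 0.25 year. Horizons that are not multiples
of `dt` are closed with one shortened final step.

**Calibration.** `calibrate_model()` minimizes the weighted sum of squared
differences between model prevalences and user-stated targets over a named
set of free parameters with box bounds (`optim`, L-BFGS-B), starting from
the supplied parameter values — deterministic, no stochastic search. Scalar
parameters are fitted directly; whole rate tables are fitted as one
multiplicative scale, which keeps the free-parameter count per target
honest. With more free parameters than targets the fit warns (ridge);
an abnormal line-search exit on such a ridge returns the better of the
start and end points rather than failing, since either is a valid
least-squares point. Fitting a country's actual parameter values is out of
scope; the module exposes calibration so users can anchor the simulation to
whatever prevalence series they trust.

## Sampling individuals

`sample_individuals()` draws `n` individuals from a multinomial over the
strata within an age range (default 15–79 years = 13 bands), with
probabilities proportional to occupancy. Sampling is **with replacement**:
occupancies are continuous masses, so there is no finite population to
exhaust. Individuals carry the five-year band, not an exact age, because
the score's age categories are the bands themselves. One explicit integer
seed per table makes every draw bit-reproducible, and the seed, source time
and frame are recorded in a provenance attribute (JSON sidecar on disk).
Survey-design features (weights, clustering, non-response) are deliberately
out of scope.

## The score estimator

`derive_score()` fits a multivariable logistic regression (IRLS via `glm`,
convergence tolerance $10^{-10}$) of the diabetes flag on categorical
covariables — age band against 15–19, sex against female, each factor
against its absence — with **no interaction terms**, keeping the score
usable on paper. Each non-reference coefficient becomes

$$\text{points} = \operatorname{round}(10\,\hat\beta)$$

with halves rounded away from zero, applied to the **full-precision**
fitted coefficient, never to a printed two-decimal version (rounding the
printed value is ambiguous exactly at half-integers, which do occur).
Reference categories are 0 by construction, so the aggregate score — the
sum of category points — starts at 0; its maximum is the sum of
per-covariable maxima, reported as-is. A negative fitted coefficient yields
negative points with a warning rather than silent truncation, which would
change the score's ranking behaviour; at survey scale (n = 5,000) weakly
informative categories can land slightly negative by sampling noise.

Separation (a covariable level perfectly predicting the outcome) is
detected and reported as an error naming the covariable, as the points for
an infinite coefficient are meaningless. Odds-ratio intervals are Wald on
the log scale, exponentiated.

## Evaluation

* **AUC** is the tie-corrected Mann–Whitney statistic computed from
  midranks; it equals the trapezoidal area under the empirical ROC step
  curve (asserted against a brute-force all-pairs count and against an
  independent ROC library in the tests). Its CI is a stratified percentile
  bootstrap — cases and controls resampled separately, 2,000 resamples by
  default, seeded, hence reproducible. No correction is made for the
  cut-off having been selected on the same sample.
* **Cut-offs.** Flagging means score ≥ cut-off. Candidates are the
  midpoints between adjacent distinct observed scores plus one beyond each
  extreme, so "flag everyone" and "flag no one" are reachable; on integer
  scores this yields the conventional half-integer cut-offs. The optimal
  cut-off maximizes sensitivity + specificity; ties break toward the
  smallest cut-off (more sensitive), the natural screening preference.
  Constrained variants return the smallest cut-off with specificity ≥ the
  requested level (maximizing sensitivity subject to it) or the largest
  with sensitivity ≥ the level. Because the extreme candidates achieve
  sensitivity 1 and specificity 1 exactly, any level below 1 is attainable.
* **Predictive values** follow the exact identities
  $PPV = se\,p / (se\,p + (1-sp)(1-p))$,
  $NPV = sp\,(1-p) / (sp\,(1-p) + (1-se)\,p)$, and proportion flagged
  $\pi = se\,p + (1-sp)(1-p)$; count-based and identity-based values agree
  to $10^{-12}$ on every confusion output. The prevalence used is the
  sample's unless the caller supplies one. Proportion CIs are Wilson score
  intervals.
* **Testing yields** are inverse stratum prevalences $1/p_s$ (persons
  tested per case found), by any grouping of sex, band and factors, on
  either an individual table (row counts) or a compartment state
  (occupancy-weighted); $p_s = 0$ is flagged not-estimable rather than
  reported as an infinite yield.
* **Comparison** of several score definitions re-optimizes each
  definition's cut-off on the common sample and reports AUC, sensitivity
  and specificity per score, restricted to shared covariables.

## The synthetic-data generator

`generator_spec()`/`generate_individuals()` produce individual tables with
known ground truth: covariates drawn independently given sex and age band
from stated marginals, and the diabetes flag from a stated logistic model.
`builtin_fixture(year)` packages one spec per projection year (2020, 2030,
2050) encoding that year's published multivariable disease model (constant
and per-category coefficients) together with the year's covariate
marginals. Sex split is even and the age-band distribution is uniform over
the 13 bands of the 15–79 frame — the underlying samples' age structure is
not published, so a declared-uniform default is used rather than a hidden
guess. A real population is younger than uniform, which is why the
fixture's emergent diabetes prevalence (≈ 24% in 2020) sits above the
published 2020 sample's 19.2%.

What the fixture does **not** emulate: correlation between risk factors
(obesity, smoking and inactivity co-occur in real populations and in the
compartmental model's joint distribution; the fixture draws them
independently unless a joint table is supplied), realistic age pyramids,
and any demographic trend between years. Consequently, recovery tests
target the generating coefficients — which the fitting stage reproduces
within sampling error, verified at n = 200,000 across seeds — and the
pipeline-level check asserts only that the derived score's AUC falls in a
plausible 0.70–0.85 discrimination band at n = 5,000, not any specific
published AUC. Passing these tests demonstrates the machinery is correct,
not that any particular population's score is reproduced.

## Problem sizes used in the test suite

Analytic identities and oracle-equivalence checks run on toy vectors and
100 random tables of up to 500 rows. Sampling and marginal-recovery checks
use $10^5$ draws (four binomial standard errors as the acceptance band).
Coefficient recovery runs at n = 200,000 — five seeds against a 3-SE
per-coefficient band, and twenty seeds for the 0.02 band on the mean —
sizes at which the expected deviations are several times smaller than the
quantities asserted. End-to-end pipeline checks use the survey scale,
n = 5,000.

## Known limitations

* The simulator is deterministic and first-order; it is a scaffold for
  sampling and calibration experiments, not a demographic forecast (no
  migration, no cohort effects, exponential band residence).
* Scores use categorical five-year age bands only; continuous-age
  modelling, variable selection, regularization and interactions are
  explicit non-goals.
* The bootstrap CI for the AUC, and all confusion-matrix CIs, ignore the
  optimism from selecting the cut-off on the evaluation sample.
* Factor independence in the generator understates the collinearity a
  model-sampled or real table would show; fitted standard errors are
  accordingly somewhat optimistic there.
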