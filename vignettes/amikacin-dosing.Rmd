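---
title: "Population pharmacokinetics and renal dosing simulation of amikacin in elderly patients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics and renal dosing simulation of amikacin in elderly patients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amikelder)
```

## The problem

Amikacin is a concentration-dependent aminoglycoside with a narrow
therapeutic index. Efficacy tracks the ratio of the peak plasma
concentration to the pathogen's minimum inhibitory concentration — a
Cmax/MIC of at least 8 predicts therapeutic success — while nephrotoxicity
tracks elevated troughs, with 4 mg/L a widely used ceiling. In patients
over 70 the drug's disposition changes: clearance falls with renal
function and the volume of distribution rises with extracellular fluid, so
dosing rules derived from younger adults misfire. The question this
package answers end to end is: *given an elderly patient's creatinine
clearance, which initial amikacin dose and interval jointly attain the
efficacy and safety targets in at least 90% of plausible patients?*

The pipeline has four stages, each exposed as tidyverse-style functions
over tibbles:

1. a structural PK model (`concentration_profile()`,
   `two_compartment_profile()`);
2. a nonparametric population estimator for sparse peak/trough
   therapeutic-drug-monitoring data (`npag_fit()`, `covariate_scan()`),
   with diagnostics (`predictions()`, `vpc()`, `bootstrap_ci()`);
3. a Monte Carlo dosing simulator (`simulate_exposures()`, `pta_table()`,
   `fta()`);
4. a renal-function nomogram builder (`build_nomogram()`).

A synthetic-cohort generator (`simulate_tdm_cohort()`) reproduces the
statistical structure of a 15-patient elderly TDM cohort so every stage is
testable without hospital data.

## Structural model and covariate model

Disposition is a linear one-compartment model with zero-order infusion
input and first-order elimination; the production path is the closed-form
superposition solution, exact and fast enough for $10^6$-scale Monte
Carlo work (an ODE integrator appears only as an oracle in the test
suite). A two-compartment bi-exponential comparator is provided for model
selection, with no covariates on its distributional parameters; with two
to three samples per subject it is not identifiable and loses on AIC.

Clearance carries the single covariate of the final model, renal function
estimated by Cockcroft–Gault:

$$\mathrm{CL} = \mathrm{CL_s} \times \frac{\mathrm{CCr}}{52.9},$$

where $\mathrm{CL_s}$ (L/h) is the clearance of a subject at the reference
creatinine clearance. The default reference is 52.9 mL/min, the value
printed in the final model equation (the cohort mean); the cohort median,
52.1 mL/min, is almost identical and can be selected via
`covariate_model(reference = 52.1)`. We deliberately do not guess which of
the two the original analysis intended — the difference is under 2% and
both are exposed.

Population parameter values used throughout as generator defaults are the
final-model estimates: mean clearance 2.25 L/h (CV 34.6%) at the reference
CCr and volume 18.0 L (CV 18.9%).

## The synthetic cohort generator

`simulate_tdm_cohort()` emulates the design of the source cohort, and its
defaults are the study conditions, not tuning knobs:

* 15 subjects; ages uniform on 71–95 y, weight 32.5–67.3 kg, BMI
  14.9–25.6 kg/m², CCr 10.9–94.9 mL/min, 60% female. Height is derived
  from BMI and serum creatinine is back-solved through Cockcroft–Gault, so
  every covariate set is internally consistent.
* individual $(\mathrm{CL_s}, V)$ pairs drawn log-normally, matched to the
  mean and CV above and truncated at 0.1×–10× the mean. The true
  nonparametric joint distribution behind the published summaries is
  unpublished; the log-normal is a stand-in that guarantees positivity and
  reproduces the printed mean/CV exactly. A truncated normal is
  selectable.
* once-daily 30-min to 1-h infusions of 200–1000 mg; a peak drawn 1 h
  after the infusion starts and troughs shortly before a subsequent dose;
  two samples per subject (three in 20%, giving 33 observations in
  expectation for 15 subjects).
* assay noise $N(0, \mathrm{SD}(C)^2)$ with
  $\mathrm{SD}(C) = 0.1 + 0.06\,C$ mg/L — a 6% proportional term for an
  immunoassay whose intra- and inter-assay CVs are within 6%, plus a small
  additive floor near the 0.8 mg/L limit of detection. Negative draws are
  resampled (truncation at zero). Values below the LOD are flagged and
  stored at LOD/2.

What the generator does *not* emulate: real TDM data have irregular
sampling times, dose adjustments mid-course, covariates measured with
error, and model misspecification (nonlinear binding, renal-function
drift). Passing recovery tests therefore demonstrate internal consistency
of the estimator under the stated model, not robustness to real-world
violations.

## Nonparametric population estimation

The population distribution of $(\mathrm{CL_s}, V)$ is estimated as a
discrete distribution — support points with probabilities — by maximum
mixture likelihood, in the adaptive-grid tradition:

1. an initial low-discrepancy grid (Latin hypercube) over
   $\mathrm{CL_s} \in [0.1, 10]$ L/h, $V \in [1, 60]$ L, bounds that
   bracket the published estimates by more than four SDs;
2. probability weights optimised by the expectation–maximisation fixed
   point of the mixture likelihood (the weight update never decreases the
   log-likelihood, which the tests assert cycle by cycle);
3. condensation (points below $10^{-8}$ of the maximum probability are
   dropped, duplicate points merged) and local expansion around survivors
   with a radius that halves whenever a cycle gains less than the
   tolerance; iteration stops when the gain is below 0.01 log-likelihood
   units at the minimum radius, or after 100 cycles.

The observation model is Gaussian with the fixed assay-error polynomial
as the SD; estimating a multiplicative error-scale factor is intentionally
out of scope here. AIC is reported as $-2LL + 2d$ with $d$ the number of
structural dimensions (2, or 4 for the comparator) — the discrete mixture
is the estimand, not a parameter vector of free knots, so support points
are not counted.

**Below-LOD observations.** The default policy is a censored-Gaussian
likelihood term, $\log P(C < \mathrm{LOD})$, for flagged observations (the
M3 convention). The alternatives — exclusion, or imputation at LOD/2 —
remain available (`blq = "exclude"`, `"impute"`), but exclusion removes
exactly the troughs of fast-clearance subjects and demonstrably biases the
population mean clearance downward by several percent in the recovery
experiments, and LOD/2 imputation only halves the damage. Censoring keeps
the information honestly and is the default.

**Covariate building.** `covariate_scan()` refits with each candidate
scaling clearance by value/median and includes a candidate when it
improves $-2LL$ by more than 3.84 (the 5% $\chi^2_1$ point) *and* lowers
the AIC, reporting alongside the $r^2$ of the base model's posterior
clearances against the candidate. Shrinkage is reported as
$100(1 - \mathrm{SD}(\text{posterior means})/\mathrm{SD}(\text{population}))$
per parameter — a standard definition, documented because the summary
table format prints a shrinkage column without defining one; it is only
asserted for its range and its noise-free limit of zero, never against any
published value.

## Model evaluation

`predictions()` returns population predictions (probability-weighted over
support points), individual posterior predictions (weights proportional to
prior probability times subject likelihood), and weighted residuals; bias
is the mean weighted prediction error and imprecision the mean squared
weighted error minus bias squared.

`vpc()` simulates each subject's own dose history (no time-after-dose
binning): parameter draws from the population distribution at the
subject's CCr, noise from the assay model, percentile bands per
observation time. Below-LOD handling is symmetric — flagged observations
are excluded and the bands are computed from quantifiable (≥ LOD)
simulated values only. Without that conditioning, bands built from the
full simulated distribution are compared against LOD-truncated
observations and the check systematically overcounts above-band troughs.
On self-simulated data the 5th–95th band contains 90% of observations in
expectation; the acceptance test checks 90% ± 3 points on a 400-subject
cohort at `n_sim = 1000`, a size chosen because cohort-level clustering
(observations share their subject's parameters) makes 15-subject cohorts
far too noisy for a ±3-point assertion.

`bootstrap_ci()` resamples subjects with replacement and refits;
non-converging replicates are dropped and counted. `association_test()`
is the Pearson chi-square on 2×2 outcome tables *without* continuity
correction — with Yates' correction the published p-values (0.1368 for
attainment vs survival, 0.0440 vs eradication, on tables reconstructed
from the printed percentages) are not reproduced; without it they are.

## Monte Carlo dosing simulation

`simulate_exposures()` draws virtual subjects at a fixed CCr and evaluates
the closed form at exactly two times: the peak 1 h after the start of a
30-min infusion, and the trough just before the second dose
(interval − 0.5 h: 23.5, 47.5 or 71.5 h). These are *first-course*
exposures — the question answered is the initial dosing regimen, not
steady state, and for an extended-interval aminoglycoside the first
interval is the decision point.

Targets: efficacy Cmax/MIC ≥ 8; safety Cmin < 4 mg/L (strict by default;
the non-strict variant is selectable and indistinguishable in a continuous
simulation); joint attainment requires both on the same draw. Fractional
target attainment averages joint attainment over an MIC frequency
distribution supplied by the user as CSV/JSON — the bundled
`mic_pa_synthetic.csv` is a clearly labelled synthetic stand-in shaped
like a wild-type *P. aeruginosa* amikacin distribution, not surveillance
data, and nothing is ever fetched from a database. MICs in the
distribution are always evaluated directly, never interpolated.

`pta_table()` evaluates the full factorial grid (doses 200–2000 mg by
200, q24/q48/q72, CCr 10–90 by 10, default 1000 subjects per cell — the
published simulation size) using common random numbers: one seeded draw
set shared across cells. Exposures are deterministic functions of a draw
given the cell, so sharing draws removes between-cell Monte Carlo noise
and makes the table's monotonicities (attainment vs dose, MIC, CCr,
interval) hold exactly rather than within noise — the property a dosing
table is read for. The seed is recorded in the output.

## Nomogram construction

`build_nomogram()` selects, per CCr, among regimens whose joint attainment
meets the threshold (90% by default, optionally also an FTA bar such as
85%) the **lowest dose**, tie-broken by the **longest interval**, and
reports NA where nothing qualifies (as happens at CCr below 30–40 mL/min).
The tie-break encodes the extended-interval aminoglycoside rationale:
when a dose satisfies both targets at several intervals, the longest
interval maximises the safety margin without losing first-dose efficacy.
Display labels for the CCr decades follow the conventional
kidney-failure–to-normal bands and are cosmetic only.

Because the generator's log-normal distribution is a stand-in for the
unpublished nonparametric distribution (and any bundled MIC distribution
is synthetic), cell-level attainment percentages and FTA values are not
expected to reproduce the published tables exactly; the reproducible
surface consists of the directional claims — 1800 mg q72h attains the
joint target at MIC 8 for CCr 40–50; 800 mg q72h attains it at MIC 4 for
CCr 30; no regimen attains it at MIC 16 anywhere on the grid — plus the
monotonicity and oracle property suites. On the stand-in distribution the
selected nomogram can differ by one dose step (e.g. 1600 mg where the
published table prints 1800 mg); the reproducibility checks therefore pin
the directional claims, not the cell values.

## Numerical choices and experiment sizes

* Closed-form profiles are exact; the test suite checks them against a
  high-accuracy ODE integration (tolerance $10^{-6}$ relative) over
  random regimens, including the two-compartment comparator and its
  vanishing-shunt limit.
* EM weight iteration stops at a $10^{-10}$ log-likelihood gain (inner),
  the adaptive cycle at 0.01 (outer); expansion radius starts at 10% of
  each parameter range and floors at $10^{-4}$.
* Recovery and covariate-selection experiments use 50-subject cohorts
  with a deliberately informative six-sample schedule
  (1, 4, 8, 12, 23.75, 25 h): with peak/trough pairs only, the troughs of
  fast-clearance subjects fall below the LOD and clearance is weakly
  identified; mid-interval samples keep every subject quantifiable. This
  is a design choice of the simulation study, stated here so nobody
  mistakes peak/trough-only TDM for an equally informative design.
* Replicate fits in tests use reduced grids (60–250 initial points) and
  capped EM iterations; single production fits can afford
  `fit_options()` defaults.

## Known limitations

* The estimator assumes the one-compartment structure and a fixed assay
  polynomial; no interoccasion variability, no covariates on volume, no
  nonlinear elimination, no renal-replacement kinetics.
* The nonparametric distribution is identified only up to what sparse
  designs can see; with two samples per subject the support is coarse and
  summaries beyond mean/SD should be read cautiously.
* First-course troughs understate steady-state troughs whenever
  accumulation is non-negligible (lowest CCr rows); the safety reading is
  correspondingly permissive there, one reason the low-CCr rows end NA.
* FTA depends entirely on the supplied MIC distribution; with the
  synthetic stand-in it illustrates the computation, nothing more.
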