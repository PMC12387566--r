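---
title: "Constructing growth references with growthlms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing growth references with growthlms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthlms)
```

## The model

Pediatric growth references summarise how a measurement (height, weight,
BMI) is distributed at each age. `growthlms` uses the LMS representation:
at age $t$ the measurement $y > 0$ follows a Box-Cox Cole-Green (BCCGo)
distribution with median $\mu(t)$, coefficient of variation $\sigma(t)$ and
Box-Cox power $\nu(t)$, so that

$$z = \frac{(y/\mu)^{\nu} - 1}{\nu\,\sigma} \;\; (\nu \neq 0), \qquad
  z = \frac{\log(y/\mu)}{\sigma} \;\; (\nu = 0)$$

is a standard-normal deviate.  $\nu$ absorbs the right skew typical of
weight and BMI ($\nu < 1$); $\nu = 1$ recovers a plain normal with
proportional scale.  Centile curves are
$\mu(t)\,(1 + \nu\sigma z_\alpha)^{1/\nu}$.  Three numerical conventions
matter:

* the $\nu = 0$ branch is taken whenever $|\nu| < 10^{-8}$; the two forms
  agree to well under $10^{-6}$ in $z$ at that threshold, so the switch is
  invisible;
* the distribution's lower truncation at $y = 0$ (and, for $\nu < 0$, the
  finite upper bound of $z$ at $1/(|\nu|\sigma)$) is ignored in the CDF and
  quantile functions, as in standard LMS practice; for growth data
  ($\sigma$ a few percent) the neglected mass is far below $10^{-10}$;
* `qBCCGo` pins the Box-Cox argument just above zero when a requested
  probability lies beyond the support bound, rather than returning `NaN`.

## Reconstructing references from printed tables

Published references usually print smoothed centile tables, not the
parameter curves behind them.  `fit_lms_point()` inverts one printed row by
least squares on the quantile scale, optimising in
$(\log\mu, \log\sigma, \nu)$ with multi-start over
$\nu_0 \in \{-2, -1, 0, 1\}$ (the SSE surface has local minima in $\nu$),
then polishing with $\mu$ profiled out, since $\mu$ enters the prediction
linearly.  When a row was generated exactly from some triplet this recovers
it to machine precision.

`table_to_lms_curve()` applies this row by row and then interpolates each
parameter across age with a Fritsch-Carlson monotone-safe cubic spline.
That interpolant reproduces the fitted parameters exactly at the tabulated
ages and cannot overshoot between the sparse adult rows, which natural
cubic splines do.  One refinement: printed cells carry up to 0.05 units of
rounding noise, and the least-squares triplet occasionally leaves a single
cell just past its rounding radius while under-using the slack elsewhere.
Each row is therefore refined from the least-squares to the minimax
(Chebyshev) solution, after which every cell of the packaged height and
BMI tables is reproduced to within 0.045 units.  Evaluation outside a
table's printed span (girls stop at 18 y, boys at 20 y) is an error, never
an extrapolation.

## Fitting references from records

`fit_lms()` estimates $(\mu, \sigma, \nu)$ curves from individual records
by penalized maximum likelihood.  Each parameter's predictor
($\log\mu$, $\log\sigma$, $\nu$) is a cubic B-spline on a power-transformed
age axis ($t^* = ((t + c)/s)^{\lambda}$; $\lambda < 1$ stretches infancy,
where growth velocity is highest), with a quadratic second-difference
penalty in the classical P-spline fashion.  Fitting is parameter-wise
Fisher scoring (the RS backfitting scheme): per observation, with
$u = (y/\mu)^\nu$,

| predictor      | score                      | working weight          |
|----------------|----------------------------|-------------------------|
| $\log\mu$      | $z u/\sigma - \nu$         | $1/\sigma^2 + 2\nu^2$   |
| $\log\sigma$   | $z^2 - 1$                  | $2$                     |
| $\nu$          | exact derivative           | $7\sigma^2/4$           |

The $\sigma$ and $\nu$ weights are the leading small-$\sigma$ terms of the
expected information; cross-derivatives are ignored, as GAMLSS backfitting
does.  Every update is guarded by step-halving on the penalized deviance,
which is therefore non-increasing across iterations, and the outer loop
stops when its relative change falls below `tol` (default $10^{-7}$).
Non-convergence after `max_iter` is reported explicitly in the
`converged` flag, never silently.

Two details were settled empirically during development and are worth
knowing:

* **Initialisation of $\nu$.**  The skewness carries very little likelihood
  information (its per-observation information is $\approx 7\sigma^2/4$,
  i.e. about 0.02 for growth data), so starting the spline at $\nu = 1$
  stalls the deviance criterion long before $\nu$ reaches its optimum.
  The fit therefore first computes a constant-parameter ML estimate of
  $(\sigma, \nu)$ given the smoothed median and starts the splines there.
* **Penalty regimes.**  Published analyses of this kind report two
  smoothness presets rather than a continuous tuning parameter.  We expose
  `"adaptive"` (default; penalty weights proportional to $n$, suitable for
  final fits) and `"rigid"` (ten-fold stiffer, for conservative
  preparatory fits).  The rigid regime additionally applies a
  first-difference penalty to $\sigma$ and $\nu$: a second-difference
  penalty leaves their linear-in-age component free, and with so little
  information in those parameters that component chases sampling noise;
  classic LMS preparatory practice treats the skewness as near-constant,
  which is exactly what the extra penalty enforces.  The adaptive regime
  keeps the pure curvature penalty so genuinely sloped $\sigma(t)$,
  $\nu(t)$ are not biased.

### Two-part models, monotonicity, diagnostics

Infancy needs far more flexibility than childhood, so height is fitted as
two overlapping part-models (infant window 0-2 y with $\lambda = 0.5$ age
transform; childhood window from 0.25 y) joined at 1.2 y; weight uses
windows below 5 y and above 3 y joined at 4.25 y; BMI uses a single model
above 1.5 y, with the age transform applied for boys and not for girls.
`stitch_models()` cross-fades $(\log\mu, \log\sigma, \nu)$ linearly over
`join ± halfwidth` (default 0.3 y, a package choice — only the join age is
conventionally reported).  The blend is evaluated analytically from the two
part-models, so stitched centiles are continuous by construction and
independent of any evaluation grid; at the join age the blended median is
the geometric mean of the part medians.  A hard switch was the obvious
alternative; the cross-fade was chosen because it keeps the centiles
$C^1$ inside the blend window and differs from a hard switch by less than
the part-models' own disagreement.

Height medians must not decrease with age.  `enforce_monotone_median()`
projects the fitted median onto the nearest non-decreasing curve by
isotonic regression on a 0.05-y grid and, when records are supplied,
refits $\sigma$ and $\nu$ conditional on the constrained median.  BMI
references are legitimately non-monotone (the adiposity rebound) and skip
this step.

`worm_plot_stats()` summarises detrended QQ plots of the residual
z-scores per age group — intercept for location misfit, slope for scale
misfit, curvature for skewness — flagging groups beyond 0.10 in intercept
or slope.  `median_velocity()` screens for over-fitting: an accepted
height fit should show non-negative velocity with a single pubertal peak.

## Data cleaning

The cleaning pass reproduces the robust percentile filters of growth
surveys: per sex and age bin, records are excluded when height lies
strictly outside $[P_{25} - 4.5(P_{50}-P_{25}),\,
P_{75} + 4.5(P_{75}-P_{50})]$ or weight outside
$[P_{25} - 5(P_{50}-P_{25})^{0.75},\, P_{75} + 9(P_{75}-P_{50})]$ — about
four robust SDs out, touching well under 0.5% of clean records.  Bins are
half-year wide to age 2 and one-year after, merged forward until each
holds at least 20 records; quartiles use the type-7 (linear interpolation)
convention.  Both the binning and the quantile rule are package choices —
sources in this field state only "sex- and age-specific percentiles" — and
the bounds depend on them, which is why they are fixed rather than
configurable.  Exclusion is single-pass (bounds are not recomputed after
exclusions) and boundary values are kept: "outside the interval" is read
strictly.

Before filtering, byte-identical duplicates are collapsed and the two
classical input errors are flagged: height/weight swaps (detected when
exchanging the values restores both into their plausible intervals —
checked before the decimal rule, because a /10 height slip also violates
the weight-below-height ordering) and decimal slips (a value beyond twice
its upper bound or below half its lower bound that a single x10 or /10
correction repairs).  Both rules are deliberately conservative; on clean
synthetic cohorts they essentially never fire.  Correction is opt-in
(`repair = TRUE`); the default excludes flagged records and reports every
action.

## Cut-offs, prevalence, representation

`derive_iotf_cutoffs()` implements the IOTF pass-through convention: the
percentile levels at which BMI 25 and 30 kg/m2 sit at age 18 define
age-varying overweight and obesity cut-off curves.  A BMI exactly on a
cut-off classifies into the heavier category (the convention is not
standardised; ours is documented).  Prevalence tables follow the usual
reporting: overweight includes obesity, analysis restricted to ages >= 2 y,
records of unknown parental origin excluded and counted.  The published
international IOTF tables are deliberately not bundled — classification
uses cut-offs derived from a fitted or reconstructed reference, and
`cutoffs_from_json()` accepts an externally supplied set.

`band_counts()` + `contingency_test()` ask whether a collection region is
over-represented in an extreme centile band, via Pearson's chi-square
(no continuity correction) and adjusted standardized residuals
$(O-E)/\sqrt{E(1-n_{r}/N)(1-n_{c}/N)}$; residuals beyond about ±2 indicate
over/under-representation.  The two table rows (below band / in band) are
disjoint by construction.  `null_rejection_rate()` checks the test's
calibration under an independent-margins null; with the default design
(groups 0.5/0.3/0.2, band probability 0.1, n = 500, so the smallest
expected cell is 10) the empirical level at $\alpha = 0.05$ sits within a
point of nominal.

## The synthetic cohort generator

No individual-level growth survey data can be redistributed, so the
package ships a generator that emulates the statistical structure of a
national cross-sectional survey, and every downstream stage is exercised
against it:

* case counts per sex, 2-year age group and source follow the published
  sampling table; within a stratum ages are uniform (the true within-
  stratum density is unpublished; uniform is the documented assumption),
  except birth-registry records, which concentrate at 0-0.1 y to mimic the
  newborn spike of real collections;
* height-z and BMI-z are bivariate normal with correlation 0.1 (no joint
  law is published; weakly positive is the documented free parameter),
  mapped through the packaged reference curves, with weight back-solved
  from BMI and height;
* collection regions follow the published region shares; parental origin
  is drawn per region from the published origin-mix table, and is unknown
  exactly for retrospective sources, as in the real data;
* origin effects act on the BMI z-score only (shift `delta`, scale
  `scale`), not on height, mirroring the finding that migration background
  associates with BMI but not height.  The defaults are solved in closed
  form from the published group prevalence pairs and the reference cut-off
  z-levels (two equations, two unknowns per group), so group-wise rates
  match the published table in expectation — no tuning involved;
* military-style records are rounded to whole centimetres and kilograms;
  all others to 0.1;
* sampled z-scores are truncated at |z| <= 3.5 (height) and |z| <= 3 (BMI),
  applied after the origin shift.  The BCCGo upper tail with $\nu < 0$
  explodes within half a sigma of its finite support bound, producing
  BMI values beyond 100 that no real dataset contains; truncating after
  the shift leaves every calibrated prevalence untouched (all thresholds
  sit below |z| = 2.3) while keeping records physically plausible.

What the generator does **not** emulate: longitudinal correlation,
measurement-device and inter-observer error structure, seasonal and
secular drift, socioeconomic covariates, or regional differences in the
height distribution.  Tests that pass on these cohorts therefore validate
the estimation machinery — marginal distributions, stratum structure,
calibrated group differences — not robustness to every artefact of real
field data.

## Problem sizes and budgets

The package's own validation uses cohorts of 10,000-50,000 records
(single-sex recovery runs use n = 20,000 over 5 seeds, the scale at which
centile recovery stabilises below the 1.5%/3% acceptance bands for
height/BMI), 10,000 replicates for the null-calibration study and 4,000
for its quick variant.  A full simulate-clean-fit-tabulate pipeline at
n = 30,000 completes in well under a minute on one CPU; the whole test
suite runs in seconds.

## Known limitations

* The exact functional form of the original age transformation and
  smoothing-parameter semantics behind published two-level smoothing hints
  are not recoverable from printed sources; both are config knobs with the
  documented defaults above.
* Reconstructed parameter curves inherit the 0.05-unit rounding radius of
  printed tables; derived quantities (for example pass-through percentile
  levels) are accurate to a few tenths of a percentile point, not exactly.
* The weight reference is not packaged (no printed table exists in the
  source material); weight models must be fitted from records.
* `sigma` and `nu` estimates near window edges carry the sampling noise of
  their free linear component under the adaptive regime; use the rigid
  regime when near-constant shape parameters are defensible.
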