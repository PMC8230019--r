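---
title: "Developmental-rate modelling of olive phenology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developmental-rate modelling of olive phenology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olivephen)
```

## The model

A phenological phase is the interval between two dated BBCH events at one
site, variety and year. Its developmental rate is the reciprocal of its
length, `DR = 1/S` (d⁻¹). The package regresses site-enlarged rates
against the mean air temperature experienced during the phase and, when
requested, the mean daylength, in three shapes:

* **linear** `DR = a + bT` — intercept `a` (d⁻¹), slope `b` (°C⁻¹ d⁻¹).
  Its x-intercept is the base temperature `T₀ = −a/b`, below which
  development is taken to be nil; `1/b` is the thermal constant of the
  equivalent degree-day model.
* **multiple** `DR = a + bT + cP` — daylength `P` in hours, `c` in
  h⁻¹ d⁻¹.
* **polynomial** `DR = a + bT + cT²` — `c` in °C⁻² d⁻¹; development is
  positive only between the parabola's roots `T_p1 < T_p2`, so it also
  stops at supra-optimal temperatures.

The model's central assumption is that temperature is the dominant driver
of the phase in question, strongly enough that one site-enlarged
calibration holds across varieties and locations. That assumption holds
for the budbreak-to-flowering window of olive in Mediterranean
conditions; it demonstrably fails for fruit-development phases, where
water availability interferes, and nothing in the machinery rescues a
phase without a real temperature response — cross-validation is the
arbiter.

Simulation uses the summing-rates method: daily rates `DR_j`, clipped to
zero outside the critical thresholds, are accumulated from the phase's
start date until their running sum reaches 1.

## Conventions and numerical choices

* **Day counting.** Day `j = 1` is the first day *after* the start event;
  the start day contributes no rate. The end date is then
  `start + S`, which round-trips exactly with observed lengths
  `S_obs = DOY_end − DOY_start`, and the calibration means `T_mean`,
  `P_mean` are averaged over the same `S` days that carry rate in the
  simulator, keeping calibration and simulation self-consistent.
* **Completion.** The phase ends on the first whole day on which the
  cumulative sum reaches 1; there is no fractional-day interpolation,
  matching the precision of field surveys. Consequences of this whole-day
  resolution are discussed under *Limitations*.
* **Clipping boundaries are strict.** At exactly `T₀` (or `T_p1`,
  `T_p2`, `T₀m`, `P₀m`) the rate is zero — which the formula gives anyway
  at the threshold itself.
* **Thresholds of the multiple model.** A plane has no single
  x-intercept, so `T₀m` and `P₀m` are defined as the intercepts of the
  two univariate projections, each holding the other predictor at its
  training-sample mean. The means are stored on the fitted model and the
  derived thresholds are serialised with it, so a reread calibration
  simulates identically.
* **Polynomial validity.** Only a downward parabola (`c < 0`) with two
  real roots defines cardinal temperatures; a fitted `c ≥ 0` is reported
  as a calibration warning and the model is withheld from simulation.
* **Daylength** follows the FAO-56 daylight-hours formulas
  (declination `0.409·sin(2π·doy/365 − 1.39)`, sunset hour angle via
  arccos with clamping at polar latitudes). The declination argument uses
  a 365-day year; day 366 maps to 365. Astronomical daylight is used
  throughout, without twilight.
* **Weather gaps.** Loading tolerates gaps; at simulation time gaps of at
  most 3 consecutive days are bridged by linear interpolation and longer
  gaps are a hard error — silent interpolation across a week of missing
  winter data would bias sub-threshold clipping.
* **Dates, not day-of-year.** All arithmetic is on calendar dates, so
  phases may cross 31 December; DOY appears only in reports.

## Calibration

`fit_dr()` is ordinary least squares of `DR_obs` on the kind's design
(`[1, T]`, `[1, T, P]` or `[1, T, T²]`). The reported r² is the squared
Pearson correlation between fitted and observed rates — the definition
that matches scatter-plot presentation of simulated against observed
values; for a plain OLS fit it coincides with `1 − SSE/SST`, and it stays
well-defined for cross-validated predictions, where the residual-based
definition can go negative. The multiple kind additionally reports an
adjusted r², penalising its extra predictor. Phase records are built from
all pairwise combinations of events observed within one
(site, variety, year), lower BBCH code first; reversed pairs are rejected
rather than inverted, because an end observed before a start is a data
error, not a negative phase. Phases covered by fewer than five distinct
sites are discarded before any fitting (`filter_phases()`), which keeps a
calibration from being a single site's microclimate in disguise. Input
tables are expected to carry one date per (site, variety, year, event);
`reduce_plant_dates()` reduces raw per-plant records by the median date
(lower median on even counts, so the result remains an observed date and
the reduction is deterministic).

## Cross-validation

`kfold_cross_validate()` shuffles a phase's records and splits them into
K = 5 folds differing in size by at most one. Each fold in turn is held
out; the model is refitted on the rest and each held-out record is
re-simulated by the summing-rates method *from its own observed start
date* and its site's daily weather — validation targets phase lengths,
not chains of phases, so errors do not propagate across events. r², RMSE
and MBE are computed per fold-run, the shuffle is repeated N = 10 times,
and the report is the ensemble mean over the 50 fold-runs. The
alternative — pooling the K validation folds of a repeat before scoring —
weights records rather than folds; per-fold-run scoring was chosen
because the ensemble-mean summary is defined over runs. One top-level
seed drives everything; repeat *i* uses the derived seed
`seed·1000 + i`, so reports are bit-reproducible and repeats mutually
independent. A phase is *cross-validated* when its ensemble r² exceeds
0.8 and its ensemble RMSE is below 7 days (both strict); the RMSE gate
mirrors the uncertainty of weekly field surveys. Held-out simulations
that never reach 1 within the horizon are dropped from that fold's
metrics; folds left with fewer than two simulated records are skipped
with a warning, and the ensemble is taken over the fold-runs that ran.

## Bundled calibrations

Six phases ship as final linear calibrations: BBCH 01→61, 07→61, 51→61,
01→65, 07→65 and 51→65, with coefficients `a` from −0.0817 to −0.0132 and
`b` from 0.0020 to 0.0075 and base temperatures between 6.7 and 10.9 °C.
The shipped coefficients are rounded to four decimals, and for two phases
(01→65 and 51→65) the base temperature recomputed as `−a/b` from those
rounded coefficients differs from the published one-decimal value by
0.1 °C (6.6 vs 6.7 and 10.8 vs 10.7). `bundled_calibration()` therefore
derives `T₀` from the coefficients it actually uses and attaches the
published value as the `t0_printed` attribute, leaving the choice to the
user instead of silently preferring either.

## Reverse modelling of budbreak

`reverse_budbreak()` accumulates rates backwards from an observed
flowering date and returns the *latest* start `s` whose forward sum over
`(s, end]` reaches 1. Forward simulation from `s` therefore completes no
later than the observed end. Whole-day completion creates an asymmetry:
the forward pass overshoots 1 by up to one final-day rate, and the
backward pass will shed leading days whose cumulative rate fits inside
that overshoot. The recovered start is hence *never earlier* than the
true one, and later by exactly the number of such leading days — zero
whenever the first day's rate alone exceeds the overshoot. Under spring
warming the first days of a budbreak-to-flowering phase carry the lowest
rates, so a lateness of a few days is typical (about 5 days on average at
the default synthetic conditions); users needing a conservative early
bound should treat the estimate as an upper bound on the start date.
This characterisation is asserted record-by-record in the test suite.

## The synthetic survey generator

Real multi-site phenological observations are not redistributable, so the
package generates its own study system with known truth
(`generate_survey()`), chosen once to emulate a late-1990s Italian
survey:

* seven sites at latitudes 37.41–43.66 °N with annual mean temperature
  `33 − 0.45·latitude` °C (≈16.2 °C in Sicily to ≈13.4 °C in Tuscany), a
  sinusoidal seasonal cycle of half-amplitude 9 °C peaking near the end
  of July, and i.i.d. daily noise of SD 1.5 °C;
* four varieties per site over 1997–1999, giving 84 records per phase,
  within the 50–85 range of the emulated surveys;
* budbreak day-of-year drawn uniformly in [30, 120], bracketing the
  observed spread of the budbreak stage; phase ends forward-simulated
  under the bundled 01→61 and 01→65 calibrations as ground truth;
* survey-date uncertainty as independent rounded Gaussian jitter of SD
  3.5 days per event (half the 7-day survey interval); jitter that would
  collapse a phase to non-positive length, or push an event out of its
  calendar year, is redrawn.

Under these defaults the emulation reproduces the scale of the real
experiment — mean 01→61 phase length ≈ 61 days with SD ≈ 21 days,
full-data calibration r² ≈ 0.85–0.92, cross-validation RMSE ≈ 3–4 days —
without any tuning against those statistics: they emerge from the
generating model, the temperature climatology and the jitter.

What the generator deliberately does **not** emulate: temporally
autocorrelated weather (heat waves, cold spells), precipitation and its
influence on fruit phases, genotype-specific rates, site microclimate
beyond latitude, observation gaps, and any chilling/endodormancy control
of budbreak timing — budbreak dates are exogenous draws. Passing tests on
synthetic data therefore demonstrate the correctness and internal
consistency of the machinery under the stated generating assumptions, not
the field validity of any calibration; the bundled calibrations carry
that evidence from their original cross-validation.

## Problem sizes in tests and the acceptance script

The shipped checks run the full pipeline at the scale of the emulated
survey (7 sites × 3 years × 4 varieties; 5 × 10 fold-runs), 1000 random
series for the simulator-versus-brute-force comparison, and 500 Monte
Carlo replicates at n = 70 for slope-recovery coverage — sizes chosen so
every property is exercised at realistic sample sizes while a complete
run stays interactive.

## Limitations

* **Whole-day resolution bounds attainable precision.** Because observed
  lengths are integers, each observed rate `1/S` sits below the
  generating line by up to the completion-day rate (< `DR²` in relative
  terms, i.e. a few percent at flowering-season rates). Coefficients
  recovered from even noise-free synthetic data therefore differ from the
  generating ones by order 1–5%, and exact recovery is impossible in
  principle; the test suite asserts recovery at this discretisation
  bound, and exact (< 10⁻⁶) recovery only on exact rate records.
* **Clipping is a misspecification for cold starts.** Phases that spend
  days below `T₀` violate `1/S = a + b·T_mean` (the regression ignores
  clipping), which degrades calibrations that include early, cold
  budbreak records — visible in the synthetic experiments and inherent to
  the method.
* **No dormancy model.** The package predicts from a given start date; it
  does not decide when budbreak becomes possible. Chilling requirements
  and endodormancy release are out of scope.
* **Phases ending away from flowering** show weak temperature response in
  the source data; the machinery will fit them, and cross-validation will
  correctly refuse to select them.
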