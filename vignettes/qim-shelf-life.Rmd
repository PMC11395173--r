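---
title: "Quality Index Method shelf-life analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality Index Method shelf-life analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qimshelf)
```

## The method

The Quality Index Method (QIM) grades fish freshness by scoring a fixed set
of sensory parameters in integer demerit points — 0 for the fresh descriptor
up to 1 or 2 for the most degraded one — and summing them into a quality
index (QI). For whole king weakfish the bundled scheme has 13 parameters in
4 groups (overall aspect, gills, eyes, anal area) and a QI range of 0–21;
the maximum score means every attribute was judged at its worst, i.e. the
panel rejected the fish.

Two properties make the QI useful beyond grading. First, it increases close
to linearly with days in ice, so an ordinary least-squares calibration
`QI = b·day + a` can be inverted to estimate how long a fish of unknown
history has been stored, and hence how much of the established shelf-life
remains. Second, combined with microbial and chemical spoilage indicators it
supports a defensible shelf-life decision for the species.

## Panel aggregation

How several referees scoring several fish become one QI per day is a
convention, not part of the method's definition. Here each sheet (one
referee × one fish) is summed to a QI and the per-day panel QI is the
arithmetic mean over sheets, with its sample standard deviation; this keeps
the panel QI on the demerit scale and matches the usual reporting of mean
demerit scores per attribute. Incomplete sheets are rejected rather than
imputed — a QIM sum with missing parameters is not comparable to complete
ones — and demerits must be integers from each parameter's descriptor range.

## Calibration and inverse prediction

`fit_line()` is plain OLS; the stored quantities are slope, intercept,
`R² = 1 − SSres/SStot`, residual SD and n. Integer QI predictions round half
away from zero and clamp to the protocol range. Inverse prediction solves
`day = (QI − a)/b` and attaches a delta-method interval,
`se(day) ≈ residual_sd/|b|`, clipped at 0 days. The delta method (rather
than a Fieller interval) is a deliberate simplification: it is accurate when
the slope is many standard errors from zero, which holds for every
calibration in this domain (R² above 0.85 on 6 points); the interval is
documented as approximate.

The "standard error of performance" of a calibration has several
conventions in circulation, so `sep()` reports all three: RMSEP, mean bias,
and the bias-corrected SEP, which satisfy
`RMSEP² = bias² + SEP²·(n−1)/n`.

## PLS1 and attribute importance

To rank which sensory attributes carry the storage-time signal, storage day
is regressed on the 13 per-day mean demerits by PLS1 with the NIPALS
recursion (`w ∝ X'y`, scores `t = Xw`, loadings and deflation per
component). PLS1 was chosen because it is exact, transparent, and exposes
the per-component weights and explained response variance that the VIP
statistic needs:

VIP_j = sqrt( p · Σ_a SSY_a w_ja² / Σ_a SSY_a ),  SSY_a = q_a²·t_a't_a,

normalised so Σ_j VIP_j² = p; attributes with VIP > 1 contribute more than
average and 1.0 is the customary selection threshold. X is autoscaled to
unit variance by default (mixed 0–1 and 0–2 attribute ranges), with a flag
to disable. The component count is chosen by leave-one-out RMSECV; with a
single latent freshness factor driving all attributes, one or two components
are expected and observed. Full-rank PLS1 reproduces OLS fitted values,
which the tests use as an oracle alongside frozen predictions from an
independent implementation.

## Indicator rules and the shelf-life decision

Indicators are named time series with units; limit rules carry a threshold,
a direction and units, which are checked at application time. The defaults
are 7 log CFU/g for mesophilic and psychrotrophic counts (reaching the limit
counts as rejection), 30 mg N/100 g for TVB-N (the stricter of the two
customary limits, 30 and 35), and 5 mg MDA/kg for TBARS (lower bound of the
customary 5–8 band). Putrescine below 10 mg/kg marks fresh fish and above
20 mg/kg low quality; the closed interval [10, 20] is classed intermediate
because the bands are defined by strict inequalities only.

Crossings are detected two ways and both are reported: the first *observed*
sampling day satisfying the rule, and the *continuous* day at which a fitted
straight line reaches the threshold. The two can disagree by up to one
sampling interval (and more when an observation departs from the trend, as
with a psychrotrophic count of 7.02 log CFU/g on day 14 against a fitted
6.80); the decision logic uses observations, the fitted crossing is
informational.

The integrated shelf-life is the greatest sampling day strictly before the
first rejection — rejection on day 14 of the grid {1, 4, 8, 11, 14, 18}
gives 11 days. Sensory rejection fires when the rounded panel-mean QI
reaches the protocol maximum (a stricter any-referee variant is available).
Amine band crossings are reported but kept out of the rejection set: the
amine bands grade quality rather than acceptability, panels cannot smell
putrescine, and in the reference study the rejection threshold was set by
the sensory and microbial evidence (day 14, hence 11 days) even though
putrescine exceeded 20 mg/kg from day 8. Users who want the stricter
reading can pass the amine rule through `integrate_shelf_life()` directly,
which is agnostic about where findings come from.

## The simulator: what it emulates and what it does not

`sim_config()` defaults encode the reference study design: sampling days
{1, 4, 8, 11, 14, 18}; 4 referees × 3 fish per day; QI trend
0.9281·day + 1.3378 (the better-behaved of the two application lots);
log-linear mesophilic (0.1229·day + 3.4642) and psychrotrophic
(0.1593·day + 4.5679) growth; linear TVB-N (0.9577·day + 8.0379) and TBARS
(0.0034·day + 0.2253) trends; and near-exponential putrescine accumulation,
whose log-linear coefficients are fitted at run time to the bundled measured
series rather than hard-coded. The microbial and TVB-N intercepts are used
with positive sign: the negative signs in the original typesetting are
inconsistent with the same study's printed endpoint values (5.7 log CFU/g at
day 18, 7.02 at day 14, TVB-N 11–28 mg N/100 g), all of which the positive
intercepts reproduce.

Panel sheets are generated from a latent freshness value
`f = qi_line(day) + N(0, referee_noise_sd)` per sheet. `f` is rounded half
away from zero to an integer target QI (clamped to the protocol range) and
apportioned to parameters proportionally to each parameter's maximum
demerit by the largest-remainder method with per-parameter caps. This
scheme was chosen over independently rounding each parameter's share
because it conserves the total exactly: a noiseless day-18 sheet on the
default line sums to 18, as it must.

No noise magnitudes are published, so they are package choices, fixed once:
referee noise SD 0.5 demerit (keeps the simulated QI-vs-day R² in the
vicinity of the reference 0.9868 — a design choice, not a claim about the
study's panel); 0.15 log CFU/g for plate counts and 1 mg N/100 g for TVB-N
(typical assay repeatability); 0.01 mg MDA/kg for TBARS; 0.2 log-scale for
putrescine (chromatography of a fast-accumulating analyte). One root seed
drives deterministic child seeds for the panel and indicator streams, so the
two are independent but jointly reproducible.

The simulator emulates the *statistical* structure the analysis assumes —
linear trends, ordinal sheets, independent Gaussian/log-normal noise. It
does not emulate referee-specific bias or drift, fish-to-fish heterogeneity
beyond sheet noise, seasonal lot effects, mechanistic growth curves
(lag/stationary phases), or censoring at detection limits. Passing tests
therefore demonstrate that the pipeline recovers what it assumes, not that
real panels satisfy those assumptions.

## Numerical choices and problem sizes

Rounding of predicted and simulated QIs is half-away-from-zero, matching
how demerit totals are read in practice. Day alignment across series is an
exact inner join (all series in a study share the sampling grid); no
interpolation. Degenerate inputs fail loudly: zero-variance x in
calibration, constant series in correlations, slope 0 in inverse
prediction. NIPALS stops early with a warning when the deflated `X'y`
vanishes (noiseless rank-deficient data) and keeps the components found.

The test suite's Monte-Carlo checks use 500 replicate panels for slope
recovery and 200 replicate studies for the QI–psychrotrophic correlation;
both complete in well under their intended runtime on a single CPU and give
Monte-Carlo standard errors comfortably below the effects being checked.

## Known limitations

The calibration is strictly linear; species or conditions with segmented QI
trajectories need a different model. The inverse-prediction interval is
first-order. PLS inference is limited to VIP ranking — no jackknife
coefficient tests. Limit rules are species- and storage-specific constants,
not temperature-dependent models. The 11-day shelf-life reproduced in the
tests is conditional on the bundled protocol and the ice-storage design the
simulator encodes.
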