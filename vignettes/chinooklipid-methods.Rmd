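---
title: "Methods: fat-meter calibration and Fraser Chinook lipid analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fat-meter calibration and Fraser Chinook lipid analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chinooklipid)
```

## The problem

Microwave fat meters estimate tissue lipid from water content at the spot
under the sensor, in somatic tissue only. Killer whales eat whole fish, so
an ecologically useful calibration must map meter readings to *whole-body*
lipid — somatic plus gonadal compartments, viscera included. This package
implements that calibration and the downstream analysis of stock-specific
and seasonal lipid variation in Fraser River Chinook at river entry, with a
synthetic-data generator standing in for the field data so every stage is
testable and reproducible offline.

## Whole-body lipid from homogenates

A homogenized fish contributes two compartments: somatic (carcass plus
viscera, ground together) and gonad. Gravimetric lipid fractions are
measured on dried tissue (somatic in triplicate, gonad in duplicate,
replicate means taken — no outlier rejection), converted to the wet basis by
`lipid_dry × (1 − water_frac)`, and combined mass-weighted:

$$L = 100\,\frac{m_s f_s + m_g f_g}{m_s + m_g}.$$

The result always lies between the two tissue percentages. GSI is kept as a
ratio (gonad/somatic) everywhere; percent-style rendering is left to I/O,
because the bioenergetics worked examples below use the ratio scale.

## The calibration

Both the reading and the measured lipid carry error, so a model II line is
the natural first family. Both the major-axis (MA) and standardized
major-axis (SMA) estimators are implemented in closed form; **SMA is the
default** because reading (meter units) and lipid (percent) live on
different scales and MA is not scale-invariant. The second family repeats
SMA on log-transformed readings. The third is a continuous two-segment
(segmented) regression in hinge form,
$L(x) = \beta_0 + \beta_1 x + \delta (x-\psi)_+$, which captures the meter's
saturation at low lipid: below the breakpoint the line is steep (the meter
compresses 2–5% lipid into readings 0.6–1.06), above it shallow.

The breakpoint is profiled out: for each candidate $\psi$ the other
coefficients are a linear solve, and the profile RSS is minimized over a
coarse grid (every midpoint between consecutive sorted unique readings,
requiring at least 3 observations per segment), then refined by
golden-section search in the bracket around the best candidate. This is
deterministic and directly checkable against an exhaustive grid, unlike
iterative segmented-regression schemes; on noise-free data it recovers the
generating parameters to below 1e−6. Rank-deficient or inadmissible
candidate sets degrade to a flagged single-line fit. Adjusted R² for the
segmented family charges 4 model df (two slopes, intercept, breakpoint).

All 21 (position combo × family) models are ranked by adjusted R² on the
same response; multi-position combos average the named positions, ties break
toward fewer positions, then lower position index (parsimony). Covariate
checks are nested-F tests: the reading × GSI and reading × mass interactions,
and a sequential ANCOVA by sex (slope homogeneity first; adjusted intercepts
only if slopes are homogeneous).

**The published coefficients.** The packaged default calibration is
β₀ = −1.973, β₁ = 6.758, δ = −6.202, ψ = 1.059, floor 0.6. The printed form
of the upper segment ("6.758 ± 6.202") is ambiguous between a slope change,
a second slope, and an uncertainty half-width; it is read here as the slope
*change*, giving an upper slope of 0.556, because the alternatives map the
maximum observed reading (16.8) to physically impossible lipid levels
(> 100%), while 0.556 maps it to ≈ 13.9%, inside the observed lipid range.
This interpretation is configurable via `piecewise_calibration()`.
Predictions are clipped to [0, 100]% and readings below the floor are
evaluated at the floor with a warning rather than an error, since field
sheets occasionally contain them.

## Survey analysis

`apply_calibration()` maps position-1 readings through the calibration;
energy density is affine in lipid. The conversion's original coefficients
are not published, so the packaged default (`table3_energy_conversion()`)
fits the line by OLS to the five MU mean (lipid %, kcal/kg) pairs of the
packaged summary table — slope ≈ 84.3 kcal/kg per percentage point,
intercept ≈ 820 kcal/kg; any externally supplied `energy_conversion()` can
replace it. Held out of its own fit, the smallest MU's mean ED is
reproduced within 0.5%, which is the package's check that the affine family
is adequate.

MU summaries report run timing as first catch, the first date at which
cumulative catch reaches half the MU total, and last catch. ANOVA + Tukey
HSD (studentized-range distribution, via `aov`/`TukeyHSD`) compares MU mean
lipid; the compact letter display uses the insert-and-absorb algorithm at
α = 0.05, with groups ordered by decreasing mean. The Spring 4_2 MU (n = 9)
is excluded from ANOVA/Tukey and slope ANCOVAs by default but kept in
summaries and in the conversion fit. A stock blocklist in
`pipeline_config()` supports dropping populations geographically atypical
for their MU. Seasonal change within an MU is an OLS regression of lipid on
day of year; because "total decline" can be read either as slope × span or
as last-minus-first weekly means, both are reported
(`total_change_pp`, `weekly_change_pp`). Slope comparisons between MUs are
nested-F ANCOVAs; the hatchery–wild contrast is a Welch t-test (the
equal-variance choice is not documented in the field protocol, and Welch is
the safer default). Weekly CPUE sums catch over effort per ISO week — the
week convention is likewise a package choice.

## Migration difficulty

Work = elevation × distance / 1000 and slope = 500 × elevation / distance
are computed per stock and *then* averaged per MU — the only aggregation
consistent with published MU-level work/slope values, which differ from the
product/ratio of the published MU mean elevation and distance. Because the
per-stock source tables are scattered across the primary literature, the
MU-level values ship as a plain-text fixture (`fraser_mu_indices()`) and are
treated as ground truth. Correlations with MU mean lipid are Pearson r with
two-sided p from the t transform on n − 2 df; with only five MUs the power
is minimal and the p-values are reported, not leaned on.

## Bioenergetics

The Discussion-style energy accounting uses: gonad mass from GSI
(`m·GSI/(1+GSI)`), gonad energy density 7.79 kJ/g, and 4.184 kJ/kcal. The
reference fish mass is interpreted as **total** mass (the default
`mass_basis`), because only that interpretation reproduces the ≈ 4720 kJ
gonadal-investment figure for an 8 kg fish with GSI rising 0.1 → 0.2; the
somatic basis is retained as an option and documents the difference. The
killer-whale prey-requirement scenarios do not model predator energetics:
the population energy requirement is back-calculated from a reference
scenario (245,000 fish/year at 8 kg and the spring-run mean energy density)
and re-evaluated at other MUs' energy densities, so requirement ratios equal
inverse energy-density ratios exactly (fall/spring ≈ 1.32).

## The synthetic-data generator

The generator defines the study conditions the tests run under.

*Calibration cohort* (`calibration_sim_config()`): 63 fish, total mass
uniform on 0.25–11.05 kg, whole-body lipid uniform on 1–13.9% (whose image
under the inverse calibration spans readings 0.6–16.8), GSI uniform on
0.01–0.17, female gonad lipid N(10.03, 1.89)%, male N(0.68, 0.36)%. The
somatic lipid fraction is solved from the target whole-body value, water
fractions follow the inverse water–lipid relationship the meter exploits,
and replicate dry-mass fractions are centred exactly on their target so the
tissue arithmetic reproduces the generating lipid bit-for-bit. Position-1
readings are the calibration inverse plus meter noise (default sd 0.2 meter
units); positions 2 and 3 add independent extra noise (default sd 0.5),
which is what makes position 1 the best single position in the ranking.
The 0.6 floor is a configurable default, not a constant, since it is an
empirical observation about the instrument.

*Survey* (`survey_sim_config()`): per-MU sample sizes 289/9/72/966/473 with
run windows taken from the published run-timing dates. Catch dates are
uniform in the window; expected lipid declines linearly in day of year —
linear because the field analysis fits linear day-of-arrival regressions.
Start/end means are the MU mean ± half the within-season decline
(5/4/5/6/4 pp), so the season-wide mean recovers the published MU means
(12.8/12.2/12.7/10.8/7.3%) under uniform dates; the residual sd around the
seasonal line is set so total spread approximates the published MU standard
deviations. Fall 4_1 draws 30% fin-clipped fish at a −0.82 pp offset,
centred so the MU-wide mean is unaffected, and its GSI rises 0.1 → 0.2
across the run. A note on counts: the published per-MU sample sizes sum to
1809 while the text reports 1566 individuals; the generator follows the
per-MU sizes and leaves the discrepancy unresolved.

What the generator does *not* emulate: gill-net size selectivity and the
alternating two-net schedule, non-uniform within-run catch intensity,
measurement dropout, misassigned stocks, and any covariance between lipid
and body size. Passing tests therefore demonstrate that the estimators
recover the structure they target at realistic n and noise — not that field
data are this clean.

## Numerical choices and degenerate inputs

Breakpoint refinement converges the golden-section bracket to 1e−10;
segments need ≥ 3 points each. Zero-variance predictors are rejected with
explicit errors; a constant response in the trend fit returns slope 0 with
p = 1 (no evidence against the null) rather than a 0/0 statistic. Tukey
letters come from pairwise adjusted p-values at α = 0.05. CSV interchange is
comma-separated UTF-8 with "." decimals and ISO-8601 dates; day-of-year is
derived on read and used in all statistics.

## Problem sizes used in the checks

The shipped tests run the generator at its study-condition defaults (63
calibration fish; 1809 survey records), 200 replicates for
breakpoint-recovery sampling behaviour, 20 seeded survey replicates for the
letter-grouping frequency, and 100–200 simulations for type-I-rate checks
of the nested-F tests.

## Known limitations

* The segmented model fixes exactly one breakpoint; no multi-break or
  Bayesian variants.
* The model II estimator used in the original calibration is not stated;
  SMA is a choice, and MA is one call away.
* The energy conversion is a five-point fit; its extrapolation below ~2%
  and above ~14% lipid is unvalidated.
* The archived field dataset's column layout is undocumented, so no loader
  for it is shipped; `read_calibration_csv()`/`read_survey_csv()` define
  the package's own schemas instead.
* Predator scenarios treat the population energy requirement as a single
  exogenous constant; no seasonal whale distribution or mixed diet.
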