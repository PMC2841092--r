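---
title: "Triangulating survey and per-capita alcohol exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating survey and per-capita alcohol exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upshift)
```

## The problem

Population surveys measure who drinks and how the volume of drinking is
distributed across sex, age and ethnicity, but they understate total
consumption badly: large national surveys typically capture 30-60% of the
adult per-capita consumption (APC) implied by sales and taxation statistics.
APC, in turn, is a reliable total but carries no information about how
consumption is distributed across people. Burden-of-disease work needs both:
alcohol-attributable fractions (AAFs) are computed from a dose-response
relative risk applied across the full distribution of grams of ethanol
consumed per day, by stratum.

`upshift` implements the triangulation of the two sources: fit a parametric
distribution to drinker consumption per stratum from the survey, then rescale
("upshift") that distribution so that the population total matches APC, and
feed the result into AAF computation with bootstrap uncertainty.

## Fitting drinker consumption

Three right-skewed, two-parameter families on $(0,\infty)$ are supported for
the volume $X$ (grams ethanol/day) among current drinkers: gamma
($k$ shape, $\theta$ scale), log-normal ($\mu$, $\sigma$ of $\log X$) and
Weibull ($\gamma$ shape, $\theta$ scale). All are fitted by maximum
likelihood: the log-normal in closed form, gamma and Weibull by
Newton-Raphson on the one-dimensional profile likelihood of the shape, with
method-of-moments starting values and a bounded golden-section fallback if
the iteration stalls (relative tolerance `1e-8`, at most 200 iterations, both
settable via `fit_control()`). Zero or negative volumes are rejected: exact
zeros belong to the abstainer categories, and `read_survey()` reclassifies
zero-volume "current drinkers" accordingly while dropping (and counting)
missing volumes. Optional survey weights enter the likelihood as frequency
weights.

Two properties matter downstream. First, the gamma MLE preserves the sample
mean exactly ($\hat k \hat\theta = \bar x$), so the fitted mean is the
empirical mean with no back-transformation error. Second, the gamma's
parameters are elementary in its moments,

$$k = (m/s)^2, \qquad \theta = s^2/m,$$

so a gamma with any prescribed mean and standard deviation is immediate.
These two facts are why only the gamma is shifted, even though the binned
chi-square comparison (`gof_table()`, 10 g/day bins up to 100 g/day plus an
open top bin) usually ranks the Weibull as the best descriptive fit.
Chi-square values are used as descriptive statistics: cells are
$(O_i - nE_i)^2/(nE_i)$ against full-precision fitted bin probabilities, no
pooling of small bins, no p-values. Bins are half-open $[l, u)$, so a value
exactly at 100 falls in the top bin.

## Upshifting

With APC converted to grams/day (`percapita_gpd()`; ethanol density 789.24
g/L and 365 days/year by default — the conversion constants are arguments,
since conventions differ slightly across sources), the coverage rate is the
survey's mean consumption over *all* adults (abstainers as zeros) divided by
APC. One constant is assumed for all strata: abstention proportions are
taken from the survey as-is, and each stratum's drinker mean is divided by
the coverage rate (times an optional `target_fraction` of 1.0/0.9/0.8 for
sensitivity analyses).

The shifted standard deviation cannot be observed, so it is predicted from a
linear regression on the shifted mean and sex (men 0, women 1):

$$\widehat{sd} = 1.1740005 \cdot m_{shift} + 1.0032064 \cdot sex.$$

These defaults were recovered by least squares from the 40-stratum published
US reference table shipped with the package (`upshift_reference()`,
`sd_regression()`): the male rows there share a single SD/mean ratio and the
female rows a single additive offset, so a through-origin fit reproduces
every tabulated SD to within 0.005% with $R^2 > 0.9999$; adding an intercept
yields an estimate statistically indistinguishable from zero, which settles
the through-origin question empirically. A consequence of the zero male
intercept is that every male stratum's shifted shape is the same constant
$1/\mathrm{slope}^2 \approx 0.726$, whatever the coverage. The coefficients
are overridable in `shift_config()` for populations where a different
mean-SD relation is appropriate.

Recomputing $k$ and $\theta$ from the reference table's printed shifted
means and SDs reproduces its printed shifted parameters up to the precision
the printed inputs allow: means and SDs are printed to 3 decimals, and
propagating a half-unit rounding error through the moment relations bounds
the reproduction error at about 0.0008 for $k$ and 0.0025 for $\theta$,
which is exactly the level of agreement observed. The tests assert the
per-row propagated bound rather than pretending the printed table carries
more precision than it does. (The reference table's printed original-fit
columns also contain a few rows inconsistent with any single coverage
constant; only the shifted mean/SD/parameter columns are used.)

## Attributable fractions

Lifetime abstainers are the RR = 1 reference; former drinkers carry a scalar
$RR_{form}$; current drinkers a dose-response $RR(x)$. Both AAF forms are
the standard component-cause expression $S/(1+S)$ with

$$S = P_{form}(RR_{form} - 1) + P_{cur} \, E\left[RR(X) - 1\right],$$

which collapses to the Levin formula $p(r-1)/(1+p(r-1))$ for a constant RR —
the package's primary numerical validation. In the categorical form the
expectation is a sum over category prevalences from the distribution's CDF.

Numerically, $E[RR(X)-1]$ is evaluated by the trapezoidal rule applied in
the exposure probability measure: the grid cell $[x_i, x_{i+1}]$ contributes
the endpoint average of $RR-1$ times the exact cell mass
$F(x_{i+1})-F(x_i)$. This choice, rather than trapezoids over
$(RR(x)-1)f(x)$ in $x$, is deliberate: the gamma densities of interest have
shape $< 1$ and diverge at the origin, where an $x$-space trapezoid cannot
converge, while cell masses remain exact. The integrator also splits the
domain at declared RR discontinuities and evaluates the right endpoint of a
cell ending at a jump by its left limit, matching the half-open category
convention; piecewise-constant RRs are therefore integrated exactly, and the
categorical and continuous forms agree to machine precision when the RR is a
step function on the category bounds. For smooth RRs the rule is second
order in the grid step (default 0.01 g/day over $(0, 300]$; both
configurable, and results move by under $10^{-5}$ between steps 0.2 and
0.01 for the log-linear fixtures used here).

Mass above the integration ceiling or above an explicit cap (150 g/day in
the conventional sensitivity analysis) is retained at $RR(\text{cap})$, so
prevalences always sum to one; `cap_mode = "truncate"` instead conditions
the distribution on $X \le \text{cap}$.

The relative-risk curves themselves are literature inputs, supplied as
configuration (`rr_loglinear()`, `rr_table()`, `category_scheme()`, ...).
The shipped log-linear fixture ($RR(x) = e^{0.01x}$, $RR_{form} = 1.3$) and
the default category bounds (men 0-40/40-60/60+; women 0-20/20-40/40+
g/day, after the standard volume categories) are illustrative: the package
makes no claim to reproduce any published disease-specific AAF, for which
the original RR sources must be supplied.

## Bootstrap uncertainty

`bootstrap_aaf()` resamples respondents with replacement within a stratum
and repeats the whole chain — status proportions, gamma refit, shift, AAF —
per replicate; the 95% interval is the percentile interval and the SE the
replicate standard deviation. The coverage constant and SD-regression
coefficients are held fixed across replicates because they derive from
external aggregate data, not from the stratum sample; the bootstrap
therefore captures survey sampling uncertainty only, not uncertainty in APC
or in the SD regression. Replicates whose resample cannot be fitted (fewer
than two distinct drinker volumes) are dropped and counted, and more than 1%
of dropped replicates is an error — a stratum degenerate enough to trip this
is too small or too homogeneous to bootstrap honestly. Each replicate runs
on its own sub-seed drawn once from the master seed, making results bitwise
reproducible and independent of evaluation order.

## The synthetic generator, and what passing tests show

`generate_survey()` draws each stratum's statuses from a multinomial and
each current drinker's *true* consumption from the stratum's gamma, then
multiplies by a single underreporting factor in $(0,1]$ to produce reported
volumes. The default 30 strata use the reference table's upshifted
parameters as the truth, a factor of 0.529, abstention proportions rising
with age and higher for women, and sizes scaled to a ~43,000-respondent
survey with plausible US population shares — loosely the conditions of the
method's published application, with no claim of demographic fidelity.

The generator reproduces exactly the mechanism the method assumes:
multiplicative, stratum-constant underreporting of a gamma-distributed
truth. Passing recovery tests therefore demonstrate internal consistency —
that fitting, coverage estimation, shifting and AAF computation invert the
assumed distortion — not that real surveys are distorted this way. In real
data underreporting is likely differential (heavier drinkers underreport
more, sampling frames miss heavy-drinking groups), which multiplicative
rescaling cannot capture; the reference application's fitted shapes
(~0.35-0.46) versus its upshifted shapes (~0.73) show real distortions are
not purely multiplicative. Differential upshifting is an explicit extension
point (`stratum_spec()` takes a per-stratum factor; the recovery harness
requires a common one only because the shift applies a single constant).

## Problem sizes and numerical choices in the test suite

The test suite exercises the study-scale conditions directly: parameter
recovery uses 50,000 draws; end-to-end recovery six strata of 50,000
respondents at factor 0.53 (shifted means recovered within 1%, AAFs within
0.2 points under the log-linear fixture); family identification 100
replicates of n = 5,000 per family (the generating family wins the
chi-square comparison in 100% of replicates); and bootstrap calibration 200
independent surveys of a 2,000-respondent stratum with 1,000 replicates
each, using a 0.2 g/day integration step (the percentile CI covers the
true-parameter AAF in ~93% of replications, consistent with nominal 95%
coverage for a percentile bootstrap at this n). The "true-parameter AAF" in
these checks is the estimand the procedure targets: the shift formulas
applied at the true drinker mean and true status proportions.

## Known limitations

* A single coverage constant across strata (differential undercoverage is
  out of scope, as is uncertainty in APC itself).
* Only the gamma family is shifted; log-normal and Weibull serve descriptive
  comparison.
* The SD regression is a cross-population empirical relation; its defaults
  were recovered from one published table and should be re-derived for
  substantially different populations.
* Survey design-based variance (strata/PSU/weight replication) is not
  implemented; weights affect fits and coverage but not the bootstrap's
  resampling unit.
* Printed reference values are reproduced only to the precision their own
  rounding allows (see above).
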