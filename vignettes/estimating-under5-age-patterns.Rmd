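---
title: "Estimating and comparing age patterns of under-5 mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing age patterns of under-5 mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(u5mcompare)
library(dplyr)
```

## The problem

Under-5 mortality in much of sub-Saharan Africa is estimated from two
imperfect source families: demographic surveillance systems (HDSS), which
follow a geographically defined population through repeated interview
rounds and record exact dates of births, deaths and migrations; and full
birth histories (FBH) collected retrospectively in household surveys such
as DHS and MICS. Both are subject to characteristic reporting errors —
under-ascertainment of deaths that occur before a household is first
enumerated in surveillance, and omission, date displacement and
age-at-death heaping in retrospective histories. Because the errors
differ by age, they distort not only the level but the *age pattern* of
under-5 mortality, which matters for any estimation pipeline that leans
on model age patterns calibrated to vital statistics from other
populations.

`u5mcompare` implements both estimators on a common computational core, a
log-quadratic age-pattern model as the external reference, comparison and
regression machinery for quantifying source disagreements, and a
microsimulation generator that produces surveillance and survey data with
*known* true mortality so every stage can be validated end to end.

## Direct estimation: the Lexis core

Both estimators reduce to the same synthetic-cohort construction:

1. Each individual's observed lifetime is split simultaneously by exact
   age and calendar time into cells defined by an age grid and a set of
   calendar periods (`split_exposure()`).
2. Within each cell, the mortality rate is deaths over person-years
   (`exposure_rates()`).
3. Rates are treated as piecewise-constant hazards and cumulated over
   nested age ranges; probabilities of dying follow as
   `q = 1 - exp(-sum(m * width))` (`cumulate_probabilities()`).

The age grid is a neonatal segment of 0–28 days followed by
completed-month segments ending at 3, 5, 12, 24, 36, 48 and 60 months.
One month of age is 365.25/12 days and one year 365.25 days throughout;
this fixes an exact correspondence between day-denominated (28 d) and
month-denominated boundaries. All intervals are half-open, `[lo, hi)` in
age and `[start, end)` in calendar time, so an event at an exact boundary
belongs to the higher segment — removing any possibility of double
counting.

The five reported quantities are neonatal `q(28d)`, postneonatal
`q(28d,12m)`, infant `q(12m)`, child `q(12m,5y)` and under-5 `q(5y)`
mortality. Because the cumulative hazard over a union of segments is the
sum over its parts, the composition identities

```
q(12m) = 1 - (1 - q(28d)) (1 - q(28d,12m))
q(5y)  = 1 - (1 - q(12m)) (1 - q(12m,5y))
```

hold *exactly by construction*, and the test suite asserts them to 1e-12
on every estimator output.

Numerical edge cases are handled conservatively: a cell with deaths but
zero exposure is an error (imputing a zero rate would silently bias `q`
downward), while a cell with neither deaths nor exposure contributes zero
hazard and is surfaced through a small-exposure flag. Any period in which
some segment has fewer than 50 person-years (a default chosen as the
scale at which a single event moves a segment rate by ≳ 2 per 100
person-years) is flagged `low_exposure` with a warning.

The surveillance estimator (`estimate_hdss()`) applies this machinery to
residency episodes, by default over 5-year calendar periods extending
backwards from January 1 following the last exit in the data; 10-year
windows are available through `period_grid()` for robustness checks. The
birth-history estimator (`estimate_fbh()`) applies the *same* machinery
to per-child episodes built from reported birth dates and ages at death,
over windows 0–4 and 5–9 years prior to the survey; children born before
a window enter it left-truncated at their then-current age, which is the
period construction's analogue of in-migration. Sampling weights, when
present, multiply deaths and person-years alike, so constant weights
cancel from every rate.

### Exposure start: entry date versus observation date

Surveillance only observes an individual from the first interview round
on or after their entry (`obs_date`). Counting exposure from the entry
date uses information collected retrospectively at that first round;
counting from the observation date (`exposure_start = "observation"`)
restricts to prospectively observed person-time and excludes deaths that
occurred before observation. Both rules are implemented; the difference
between them is itself a diagnostic of left-censoring problems and is
exercised by the acceptance checks.

## The synthetic-data generator

`simulate_population()` draws a uniform stream of births over the
calendar span, assigns each child a latent death age from the
piecewise-exponential law of a configurable hazard schedule, adds
constant-hazard out-migration and a Poisson stream of in-migrant under-5
children, and emits one residency episode per uninterrupted spell.
`apply_surveillance()` overlays an interview calendar (rounds on the
first of the month every `interview_interval_months`) and drops
individuals who die before their first observation with probability
`1 - ascertainment`. `simulate_fbh_survey()` interviews the synthetic
mothers and transcribes each child, then applies the three retrospective
error processes.

The default hazard schedule is calibrated to a plausible high-mortality
setting: neonatal mortality of about 31 per 1,000 live births, infant
about 79, under-5 about 130. Two modelling choices deserve emphasis:

- **The neonatal hazard is front-loaded.** The schedule splits the
  neonatal period at day 7 (1.2 deaths per person-year in week one
  against 0.15 thereafter), as early neonatal deaths dominate real
  neonatal mortality. This also means the hazard is *not* constant within
  the 0–28-day estimation segment, which is exactly why exposure counted
  from the observation date yields lower neonatal estimates: post-
  observation person-time disproportionately samples the lower hazard
  after week one. With a within-segment-constant hazard the two rules
  would agree in expectation and the sensitivity analysis would have
  nothing to detect.
- **Error magnitudes are nominal.** No data source quantifies the error
  processes, so their probabilities all default to zero and must be set
  explicitly for bias studies. The error mechanisms are: omission of dead
  children with class-specific probabilities (neonatal / postneonatal /
  child age at death); backward displacement of birth dates across the
  5-year pre-survey boundary (the boundary of the window in which surveys
  collect detailed health data), landing a uniform jitter before it; and
  heaping of reported ages at death onto the central ages "1 month"
  (exactly 28 days, catchment ±14 days) and "12 months" (exactly one
  year of age, catchment ±61 days). The 12-month heap target is one year
  *of age* — the completed-12-months code — so that upward-rounded deaths
  from 10–11 months genuinely cross the infancy boundary, which is the
  distortion of interest.

Simplifications relative to real populations: fertility is a fixed
stream, not a process; mothers are synthetic (children assigned uniformly
at a configurable mean parity) and all survive to interview, so
maternal-survival selection is absent; out-migrants do not return;
in-migrant ages at entry are uniform on 0–59 months as a stand-in for the
standing population's age distribution; there are no stillbirths and
hence no stillbirth/early-neonatal misclassification. Passing tests on
these data therefore validate the *estimators and comparison machinery*,
not the full error structure of any real HDSS or survey.

Internally time is a continuous day count from 1970-01-01. Episode and
birth-history files round dates down to whole days on write (ISO-8601);
tests of exact arithmetic operate on the in-memory continuous
representation.

## The log-quadratic age-pattern model

The reference model expresses, for each model age `x` below 5 years,

```
ln q(x) = a(x) + b(x) ln q(5y) + c(x) (ln q(5y))^2 + v(x) k
```

with the level `q(5y)` and a scalar shape parameter `k`; at `x = 5y` the
identity `a = c = v = 0, b = 1` is imposed exactly. Fitting
(`fit_logquad()`) proceeds in two stages: per-age least squares of
`ln q(x)` on the quadratic in `ln q(5y)`, then a rank-1 SVD of the
residual matrix to extract the shape direction, scaled so the per-table
scores `k` have unit sample variance and oriented so larger `k` means an
older age pattern (`v` at 12 months non-positive). With noiseless tables
whose shape scores are orthogonal to the stage-1 design, this two-stage
estimator recovers the generating coefficients exactly — the generator
`synthetic_life_tables()` applies that orthogonalization so coefficient
recovery is a sharp (1e-8) test rather than a statistical one.

Level solving (`solve_level()`) inverts the model by bisection on
`ln q(5y)` to a relative tolerance of 1e-10, after verifying that
`b + 2c ln q(5y)` keeps one sign over the bracket (the quadratic must be
monotone there for the inverse to be well defined). The packaged default
coefficients are synthetic — calibrated to a plausible vital-statistics
age pattern and shipped as a labelled CSV — because no published
coefficient table is bundled; they make the package self-contained for
demonstrations, curve overlays and generative testing, and any user
coefficient file or fitted model can be substituted.

`indirect_curves()` reproduces the indirect construction used to draw
model bounds on age-pattern scatter plots: anchor a predefined neonatal
(or infant) probability, solve the level for each shape parameter,
predict infant (or under-5) mortality, and derive postneonatal (or child)
mortality. Both the subtraction (`q12m - q28d`) and conditional
(`(q12m - q28d) / (1 - q28d)`) scales are implemented; subtraction is the
default as the procedure is usually stated that way, and the two differ
by the factor `1/(1 - anchor)`. Default shape parameters are `k = 0`
(central), ±1 (inner bounds) and ±2 (outer bounds), chosen because the
fitted `k` is standardized to unit variance, making these one- and
two-standard-deviation patterns.

## Comparison and analytics

`mortality_ratios()` computes child-to-infant (`qchild/q12m`) and
postneonatal-to-neonatal (`qpnn/q28d`) ratios, flagging zero denominators
as undefined rather than emitting infinities; abridged sources without a
neonatal split simply carry an undefined neonatal ratio. Distribution
summaries use the median and interquartile range under the
linear-interpolation quantile rule (R type 7), with groups of fewer than
3 flagged. Medians are compared with Mood's median test — a 2×2 table of
counts above/not-above the pooled median, continuity-corrected chi-square
— with Fisher's exact test as the small-expected-count fallback and a
Wilcoxon rank-sum alternative behind a flag; the choice of nonparametric
test is a design decision, as is the quantile rule.

`match_compare()` pairs surveillance strata with survey regions through
an explicit label table (geographic matching is data curation, not
computation, so labels are inputs) and computes, for identical periods
only, the relative percentage difference

```
RPD = 100 (HDSS - FBH) / ((HDSS + FBH) / 2)
```

per quantity: antisymmetric, bounded in [−200, 200] for non-negative
inputs, positive when the surveillance estimate is higher, undefined
(dropped, with a note) when both values are zero.

Data-quality covariates: `digit_preference_id()` is the Index of
Dissimilarity between the observed day-of-month distribution of reported
deaths (days 1–31) and the calendar-frequency expectation 12/365 for days
1–28, 11/365 for days 29–30, 7/365 for day 31 — half the summed absolute
deviation, computed on proportions (so invariant to the death count) and
using the non-leap 365-day denominator even for leap years.
`fbh_quality()` is a deliberately simple composite of three sub-indices
per region — date-of-birth incompleteness, 12-month age-at-death heaping
(deaths at the nearest-month age 12 over the mean of months 10, 11, 13,
14), and boundary displacement (births in the year just before the
5-year boundary over the year just after) — combined as a mean of
z-scores across the input set. It is a labelled simplification of the
survey-quality indices used in the literature, defined concretely so it
is computable and testable from the package's own record format.

`rpd_ols()` regresses relative differences on fieldwork, context and
quality covariates through ordinary least squares (`stats::lm`), with
complete-case analysis (drops logged), the African region factor
releveled to an Eastern reference, t-distribution p-values (samples here
are of order 10^2, so normal p-values would be anticonservative), and a
`bivariate_screen()` implementing the "strongly associated" inclusion
rule as an explicit threshold flag, default p < 0.10, rather than a
hard-coded judgment.

## Problem sizes and runtime choices

The bundled tests validate the Lexis core against a brute-force per-day
enumeration oracle on 500 randomized episodes, recover generating hazards
from a simulation of 100,000 births (judged at 3 binomial standard
errors), and check cross-estimator agreement on populations of roughly
60,000 births. The 100,000-birth recovery check simulates ten years at
10,000 annual births and estimates the most recent 5-year window: under
that stationary design every age segment in the window is fed by cohorts
at all ages, so each segment's death count carries the information of the
full birth cohort and the binomial tolerance is exact rather than
approximate. The acceptance script (`scripts/acceptance.R`) uses 15-year
simulations at 4,000 annual births, sizes at which all Monte-Carlo checks
sit comfortably inside their 3-standard-error tolerances while the whole
script runs in seconds.

## Known limitations

- The generator's error menu is mechanism-faithful but
  magnitude-agnostic; it cannot say how large real biases are, only which
  direction each mechanism pushes each quantity.
- No variance estimation accompanies the direct estimates (no jackknife
  or design-based intervals); comparisons rely on Monte-Carlo reasoning
  in the synthetic setting.
- The log-quadratic default coefficients are synthetic; substantive use
  requires fitting to real life tables via `fit_logquad()` or supplying a
  coefficient file.
- Survey-design features (clustering, stratified weights beyond a scalar
  per record) are out of scope; weights enter only as multiplicative
  record weights.
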