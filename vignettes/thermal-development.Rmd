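---
title: "Modeling temperature-dependent development with thermodev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling temperature-dependent development with thermodev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermodev)
```

## The model and its assumptions

Poikilotherm development proceeds at a temperature-dependent rate
*r*(T) = 1/D(T), where D is the mean number of days to complete a stage at
constant temperature T. `thermodev` works throughout on treatment means —
one (stage, sex, temperature) cell summarised as mean ± SE with a cohort
size — not on individual records. Rates are the reciprocals of the mean
durations ("rate of the mean"), the convention used when only published
summary tables are available; the reciprocal of a mean is not the mean of
reciprocals, so analyses based on individual-level data can differ slightly.

Two regimes are modeled:

* **Linear (degree-day) regime.** Between the lower threshold and the
  optimum the rate is nearly linear in T. `fit_common_linear()` estimates
  *r* = a + bT by ordinary least squares and derives T₀ = −a/b, K = 1/b.
  `fit_ikemoto_takai()` fits the equivalent duration form D·T = K + t·D
  (OLS of D·T on D, as originally proposed; no reduced-major-axis variant),
  which weights the long cold-temperature durations more heavily and often
  fits summary data better. Standard errors for T₀ and K are first-order
  delta-method transforms of the OLS coefficient covariance; published SEs
  computed by unknown methods are not reproduction targets. The default
  fitting range is 15–27 °C, configurable: rate data at 30–34 °C leave the
  linear regime and would bias the threshold.

* **Non-linear regime.** Twenty classical models cover the whole dome (see
  `model_registry()`). The printed equations in compilations of these
  models are frequently corrupted (dropped radicals and exponents, sign
  flips); the catalog implements the canonical published forms: Brière-1
  with a square root, Brière-2 with exponent 1/m, Lactin-2 with a signed
  additive λ (fitted λ is typically negative), Janisch as the duration
  model D = (D_min/2)(e^{k(T−T_opt)} + e^{−λ(T−T_opt)}), and
  Sharpe–DeMichele as the six-parameter biophysical fraction evaluated in
  Kelvin. Duration models are exposed on the rate scale (1/D);
  `evaluate_duration()` returns the native duration where one exists.

Three catalog facts matter for interpretation. Equation-16 and
Kontodimas-16 are one functional form listed twice, and the three-parameter
Lamb entry collapses onto the same Gaussian family as Taylor — both pairs
are kept as distinct entries because the literature reports all four, and
model-selection ties between the members of a pair are expected and benign.
Janisch's two exponential branches can be swapped (k ↔ −λ) without changing
the curve, and Enkegaard's form (a + bT)e^{−(c+dT)} has a continuous
scale/offset redundancy; both models fit and predict normally, but their
raw parameter vectors are not individually identifiable — comparisons
should use the identifiable combinations.

## Fitting engine

`fit_model()` minimises the residual sum of squares inside per-parameter
box bounds wide enough for realistic arthropod data (temperature-like
parameters in [−30, 120] °C). The search is a seeded Latin-hypercube
multistart (64 starts by default; scale parameters spanning many decades
are sampled and optimised on the log scale), bounded quasi-Newton descent
from every start, then a damped Gauss–Newton (Levenberg–Marquardt) polish
of the best candidates with central-difference Jacobians. The polish is
what makes noise-free synthetic data come back at machine precision
(RSS below 1e−30), which the property tests rely on. Ties in the final
loss are broken toward the smaller parameter norm; results are
deterministic given the seed. A fit that finds no valid optimum is returned
flagged (`converged = FALSE`), never raised, so batch runs always complete.

Threshold-type models carry an ordering constraint (t_min < t_max;
T_L < T_H for Sharpe–DeMichele) enforced through the objective. Without
it, the signed-power extension of the Brière family admits mirrored optima
in which both factors change sign — slightly lower RSS, meaningless
thresholds.

Goodness of fit follows the least-squares conventions used in this
literature: AIC = n·ln(SSE/n) + 2p with p counting every parameter
including intercepts, and R²_adj = 1 − [(n−1)/(n−p)](1−R²). With six
temperature means, a six-parameter model leaves R²_adj undefined (n = p);
it is reported as `NA`. An exact interpolation (RSS = 0) has no finite
least-squares AIC and is reported as −Inf with a warning; in rankings it
simply sorts first and the p-then-name tie-break applies.

## Cardinal temperatures

* **T_opt** uses the "graphical method": argmax on a 0.25 °C grid, the
  resolution at which published optima are conventionally read (every
  printed Brière optimum sits on a quarter degree); a golden-section
  refinement to ~1e−4 °C is reported alongside. For threshold models the
  search is confined between the model's own thresholds, because squared
  factors rise again outside them. A lattice argmax of a unimodal curve is
  guaranteed to be one of the two lattice points adjacent to the true
  optimum — within one grid step, usually within half a step, but a
  strongly skewed peak can legitimately pick the farther neighbour, which
  is why the agreement tests assert the one-step bound.
* **T_max** is the smallest zero of the raw (unclipped) rate above the
  optimum, by scan-and-bisection to 1e−12 °C; where a factor of the model
  vanishes at a fitted parameter (Brière, Kontodimas/Equation-16, Logan-6,
  Lactin-1, Bieri-2) the parameter identity is reported and coincides with
  the root. Curves that never return to zero (Sigmoid and friends) report
  `NA` with a diagnostic rather than a fabricated threshold. Fitted upper
  thresholds outside 30–50 °C are flagged implausible but reported —
  published fits do produce 60–70 °C values.
* **T_min** is the largest zero below the optimum; for the
  quadratic-factor models the curve touches zero without crossing, so the
  parameter identity is used. Many models have no lower intersection at
  all; these are `NA` by design, matching the published observation that
  such models cannot estimate the lower threshold.

## Degree-day forecasting

`forecast_emergence()` accumulates daily degree-days with the simple
average method, max(T_d − T₀, 0), no upper cutoff, and reports the first
day the running sum reaches K. The source analysis proposes degree-day
forecasting without fixing an accumulation rule; the simple method is the
defensible default for constants estimated from constant-temperature data,
and the forecaster exposes both linear models' constants rather than
blending them. At constant T the completion day is exactly
ceil(K/(T − T₀)).

## The synthetic-data generator

`simulate_development()` emulates the published experimental design: a
handful of constant temperatures, cohorts of tens to low hundreds of
individuals, small standard errors, and complete failure at extreme
temperatures encoded as `developed = FALSE`. Individual durations are drawn
lognormal with median 1/r(T) — positive support and the right skew for
development times — with a coefficient of variation defaulting to 0.1,
which reproduces the SE/mean magnitudes (≈0.01–0.05) of the published
cohort table. The true inter-individual variance is unknowable from a
mean ± SE table, so the CV is a stated stand-in, not an estimate. Integer
day rounding (`daily_census = TRUE`) is off by default because it breaks
noise-free recovery; switch it on to emulate the daily-observation process.
A green recovery test therefore establishes that the estimators invert the
generator's world — lognormal individual noise around a true catalog curve
— not that field data meet these assumptions (no mortality, no sex
differences, no fluctuating temperatures).

## Numerical and design choices

* n = 6 temperature means is the observation count for non-linear GOF
  statistics, matching the published adjusted-R² values and the undefined
  entry for the six-parameter model.
* Sex handling: the analysis defaults to pooling female and male cells by
  cohort-weighted means (per-sex runs are a config switch); which pooling
  produced the published non-linear tables is unstated, so refits are
  expected to approximate, not equal, the printed estimates. Egg-to-adult
  ("total") durations are stored as the directly published totals, not
  stage sums — the two differ by up to 0.2 d because the published totals
  come from individual-level data.
* Degenerate inputs fail loudly and specifically: empty slices, duplicate
  (stage, sex, temperature) triples, constant durations in the
  Ikemoto–Takai fit, temperatures at or below the threshold in degree-day
  arithmetic, non-positive rates at a requested simulation temperature.
* Scaled-down test budgets: the Monte-Carlo bias property runs 150 of the
  nominal 500 replicates in the module suite (the full 500 in the
  acceptance suite), and the noisy-recovery and model-selection-ranking
  properties run ~10 seeded replicates per case instead of 100, with
  thresholds adjusted to the smaller counts.

## Known limitations

Fits use treatment means without weighting (the source analysis states no
weights); SE-based weighting would change estimates for strongly unbalanced
cohorts. Parameter uncertainty for non-linear fits is not computed
(the published tables print none); a residual-bootstrap would be the
natural extension. The forecaster ignores upper-threshold cutoffs and
fluctuating-temperature effects. Published regression tables for this
dataset are not exactly recoverable from the published means — they were
fitted on unavailable individual-level or differently pooled data — so the
pipeline treats them as approximate references, and model selection on
refits can rank models differently than the published analysis did.
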