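---
title: "Refractometric bioprocess monitoring, pH probing and pH-constrained FBA: methods"
author: "patflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refractometric bioprocess monitoring, pH probing and pH-constrained FBA: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patflux)
```

## Scope

`patflux` implements a complete analysis chain for upstream mammalian
bioprocesses monitored by an in-situ refractometric probe: a synthetic
plant with known ground truth, derivation of the metabolic rate index
(MRI) from the process trend index (PTI), preprocessing (imputation,
missingness gating, condensation), feature similarity analysis,
forecasting harnesses, scripted and autonomous pH parameter probing,
and a constraint-based metabolic modelling core in which extracellular
pH enters flux balance analysis (FBA) as a bicarbonate-export
constraint. This vignette records the models, the tunable parameters,
the numerical choices, and the design decisions that were genuinely
open.

## The synthetic plant

All signal, forecasting and control stages are exercised against a
simulated bioprocess, because the measured campaigns behind this class
of experiment are not publicly deposited. The generator
(`simulate_culture()`) emulates the study conditions rather than any
particular dataset:

* **Sampling.** SCADA records once per minute (18 channels: elapsed
  process time, cumulative alkali/air/CO2/N2/O2, measured dO/pH/
  stirrer/temperature, four gas flow rates, four set points); the probe
  records EPT, PTI and MRI every 5 s. Runs default to 68 h, inside the
  66.15-69.25 h range such processes occupy.
* **Activity.** Ground-truth metabolic activity is a unimodal function
  of pH: a Gaussian bump (amplitude 2 RU/min, width 0.25 pH units)
  centred on the optimum pH 6.40, over a baseline of 1 RU/min. The
  bump-plus-linear-baseline family is configurable, but the default
  baseline slope is 0 so that the curve's maximum sits exactly at
  `ph_peak`; a tilted baseline would shift the analytic maximum off
  the nominal optimum and break the contract that the optimum is the
  recoverable ground truth. Only the *ordinal* facts are treated as
  known - lower pH gives higher activity down to an optimum near
  6.40 - so the quantitative shape is a package choice.
* **PTI and MRI.** PTI is the cumulative time integral of activity,
  scaled by a three-phase multiplier (0.6 / 1.0 / 1.4) switching at two
  induction events (24 h and 44 h), plus a 40 RU step at the second
  induction representing a large volumetric bolus, plus additive
  Gaussian noise (default sigma 2 RU, chosen so that replicate-level
  variability is of the order of the ~10% coefficient of variation
  reported for such probes). The instrument's true PTI-to-activity
  transfer function is not published; the integral model is an
  assumption and is stated as such.
* **pH actuation.** A first-order lag (default time constant 15 min)
  toward the clamped setpoint, with a hard floor at pH 6.40 - the
  acidification method (CO2 sparging) cannot drive the culture lower -
  plus a controller dead-band (0.20 pH for passive runs, 0.02 for
  probing runs) inside which the culture drifts acid-ward at
  10^-4 pH/min. Occasional PID sluggishness is represented by a
  seeded 20% chance, per setpoint segment, of a doubled time constant.
* **Growth.** Exponential growth with a pH-dependent specific growth
  rate interpolating 0.040 1/h at pH 7.0 down to 0.031 1/h at the
  optimum, encoding the observed growth suppression at low pH.
* **Gas pattern.** Air inflow rises steeply below pH ~6.7 (a
  CO2-stripping surrogate); a low-pH run accumulates roughly twice the
  air of a matched pH-7 run. Titres and particle counts are emitted as
  configured endpoint summaries only - the generator makes no
  mechanistic claim about vector production.

What passing tests on this plant do **not** show: anything about real
probe optics, real PID loops, or real HEK293T metabolism. They show
that the analysis operations are correct on data whose ground truth is
known and whose qualitative structure matches the application.

## MRI derivation

MRI is defined as the first derivative of a second-order polynomial
fitted locally to the raw PTI signal. `compute_mri()` fits a centred
least-squares quadratic per window and returns the analytic derivative
at the window centre, in RU/min. For a symmetric window the quadratic
term is orthogonal to the linear one, so interior points reduce to a
linear-slope convolution; edge points shrink to one-sided windows and
solve the full 3x3 normal equations. The window length is not
published; the default of 61 points (about 5 min at 5 s sampling) is a
package choice and is configurable. Whether the vendor filter is
centred or causal is also unstated: centred is the default and a
trailing-window (causal) variant is available via
`mri_params(centered = FALSE)`. The filter is linear in its input and
exact on quadratics; both properties are tested against an independent
per-window regression oracle.

## Preprocessing

* **Imputation** (`impute_series()`): isolated single missing points
  are filled by a centred simple moving average over the two nearest
  observed neighbours on each side; contiguous sections are filled by
  Kalman smoothing on the state-space representation of an ARIMA
  process fitted to the observed series. Order selection is a bounded
  AIC grid (p, q <= 2, d <= 1 for imputation), with differencing
  chosen first by a variance-reduction heuristic; the approach is
  named in the field, the exact orders are not, so the bounds are a
  runtime-motivated package choice. If no ARIMA fit converges the gap
  falls back to linear interpolation, and the report says so per gap.
* **Gate** (`missingness_gate()`): series with strictly more than 15%
  missing data are excluded - the boundary is strict because the rule
  is worded as "more than 15%", so exactly 15% is kept.
* **Condensation** (`condense_to_minutely()`): 5 s probe data are
  averaged per minute over non-missing cells; an all-missing minute
  stays missing.

## Feature analysis

Dynamic time warping (classic dynamic programming, symmetric step
pattern, absolute local cost, no window constraint, optional
z-normalisation off by default) and Pearson correlation quantify the
similarity of each online channel to MRI. A channel with zero variance
has mathematically undefined correlation and is reported as `NA`;
DTW distances above a display cap (default 6000) are flagged but not
truncated. Feature selection drops (a) channels constant across all
runs, (b) channels without temporal variation within runs (scaled
variance below 10^-12), and (c) one member of each pair with |r| at or
above 0.95, keeping the member more correlated with the target and
breaking exact ties by dropping the later-sorting name, which makes
the result invariant to channel order. The collinearity threshold that
was actually used in the motivating analysis is not printed; 0.95 is a
documented default, not a claim.

## Forecasting

`make_windows()` builds exhaustive sliding windows (feature and target
window lengths may differ; each target starts one step after its input
window ends); `shuffle_windows()` permutes them reproducibly. The
sequence model is pluggable behind a `fit`/`predict` estimator
contract: a deterministic linear least-squares baseline and an
order-sensitive single-pass stochastic-gradient linear learner are
bundled, and gradient-boosted trees (xgboost) back the tabular soft
sensor. The recurrent network used in the motivating work sits behind
the same contract but is deliberately not bundled - its layer sizes
and training schedule are unpublished, and the package's tests must be
deterministic. Scaling is per-channel min-max fitted on the training
span only. "Stacked" cross-validation is interpreted as
expanding-window time-series splits - training always precedes
validation - since no further specification is given.
`univariate_forecast()` fits an auto-selected ARIMA (p, q <= 3,
d <= 2) on one hour and forecasts the next hour.

## Autonomous pH probing

The scripted mode replays a schedule of setpoint changes (with
mirrored variants to control for order effects). The autonomous mode
starts at pH 6.60 at 26 h, always steps **down** first, and thereafter
repeats the previous direction when the trailing-window MRI improved
by more than 1% and reverses otherwise, clamped to bounds; decisions
use the *achieved* pH, not the commanded setpoint, so an actuator
pinned at its floor still yields correct reasoning. Decision cadence
defaults to 90 min with a 30 min trailing MRI assessment excluding the
10 min post-change blackout; a fully-missing window defers the
decision one cadence. These cadence numbers are package defaults (the
probing is only described as "periodic"); the underlying vendor logic
is proprietary, and this rule implements the described behaviour, not
any patented internals. Near the optimum the expected MRI difference
per 0.05-pH step is comparable to the 1% improvement tolerance, so
small-step probing ends within about one step of the optimum rather
than on it - matching the qualitative outcome that the small-step
strategy settled one step high.

## Metabolic modelling

`metabolic_model` objects carry metabolites, reactions with bounds in
mmol/(g CDW h), an objective reaction and annotation tags; they load
from a documented JSON schema or from SBML Level 3 with FBC bounds, so
externally curated genome-scale models can replace the bundled toy
network. FBA maximises the growth/demand flux subject to S v = 0 and
bounds; FVA reports per-reaction flux ranges at a configurable
optimality fraction. The LP layer is a dense two-phase primal simplex
with Bland's anti-cycling rule, written for the package because the
target problems are small (tens of reactions) and the solution must be
deterministic and dependency-free; it is certified in the test suite
against exhaustive vertex enumeration of the flux polytope on all
bundled small networks, to 10^-9. Degenerate alternative optima are
reported as an arbitrary optimal vertex - FVA, not FBA, is the tool
for uniqueness questions.

The bundled ~50-reaction toy network covers glycolysis (with all
glycolysis/gluconeogenesis-shared steps tagged), PEPCK and FBPase, a
bidirectional triosephosphate isomerase, pyruvate-alanine/serine
links, a lumped TCA cycle and oxidative phosphorylation,
extracellular carbonic anhydrase, Na+/K+-utilising transport, and a
biomass assembly with an ion-requiring variant. It conserves carbon
exactly in every internal reaction (checked at load; lumped biomass
and exchanges are exempt). The base model deliberately lacks Na+/K+
exchanges so that every ion-utilising reaction is provably
flux-blocked until `add_ion_exchanges()` restores them. The network is
a self-consistent fixture, not a reduction of any published
reconstruction, and supports qualitative properties only.

**pH as a constraint.** `derive_ph_constraint()` converts the culture
pH to a molar proton concentration A = 10^-pH and the fixed per-cell
proton export flux q to a concentration B = q X dt 10^-3 (biomass
density X in g CDW/L over a reference interval dt, both explicit
parameters; the conversion factor used by the original analysis is not
published, so dimensional consistency fixed the form). Because B must
exceed A, the surplus acid is neutralised mole-for-mole by bicarbonate
export, whose flux (B - A)/(X dt 10^-3) is applied, together with the
proton export, as equality bounds on the H+ and HCO3- exchanges. At
fixed proton export the bicarbonate efflux increases strictly with pH.
The numeric value of the fixed proton export is likewise a parameter
(default 1 mmol/(g CDW h) in examples). Whether the original equality
replaced or complemented an existing bicarbonate bound is unknown;
here it replaces both bounds of the tagged exchange.

**Gluconeogenesis blocking** restricts shared reactions to the
glycolytic direction, leaves TPI bidirectional and zeroes PEPCK and
FBPase; it can only shrink the feasible set, so the growth objective
never increases. **Amino-acid bound tightening** iterates FVA and
clamps any tagged amino-acid exchange whose feasible range exceeds the
flux equivalent of typical media concentrations (default +/-1, with
+/-0.5 for a tagged subset), logging every round. **Exchange fluxes
from offline data** use q = (c2 - c1)/(Xbar (t2 - t1)) with Xbar the
log-mean of the endpoint biomass densities (exact under exponential
growth) and 514 pg cell dry weight per cell; uptake is negative -
secretion positive is the package-wide sign convention.

## Numerical choices and degenerate inputs

LP pivot tolerance 10^-9 with finite box bounds (+/-1000 plays the
role of an open bound, as is conventional); FVA values below solver
noise (~10^-10) are reported as-is and tests compare at 10^-7.
Constant training series short-circuit the ARIMA search (a constant
forecast). An all-missing series cannot be imputed and errors. The
missingness gate is strict at its boundary. `actuate_ph()` clamps to
the floor after the exponential update, so a start below the floor is
lifted to it. Seeds: every stochastic component draws from an explicit
seed in its configuration, through a local RNG stream that leaves the
caller's RNG state untouched.

## Problem sizes used in the checks

The test-suite and acceptance checks run the full 68 h plant at native
resolution (48,961 probe samples) for the signal stages; forecasting
benchmarks run on 4-minute condensed grids; controller
parameter-recovery uses 20 seeded closed-loop runs; LP certification
enumerates vertices on networks of at most 8 reactions and Monte-Carlo
imputation uses 50 replicate series of 300 points. These sizes were
chosen as the smallest that still exercise every code path at the
plant's realistic scale.

## Known limitations

* The plant is phenomenological: no mechanistic gas transfer (kLa), no
  mechanistic vector-production model, no instrument calibration
  (RU are opaque relative units).
* The toy network cannot reproduce genome-scale flux values; all
  modelling claims tested on it are structural/qualitative
  (blocked-versus-active reactions, sign flips, difference counts).
* The bundled forecasting estimators are linear; conclusions about
  deep sequence models do not transfer beyond the estimator contract.
* The autonomous probing rule is a faithful implementation of the
  *described* behaviour of the commercial controller, not of its
  internals.
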