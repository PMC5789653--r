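---
title: "Set points or equilibrium points: models, simulators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Set points or equilibrium points: models, simulators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equipoint)
```

## The question

Textbook homeostasis says each individual defends a *set point*: a target
level of calcium, glucose or free thyroxine that control mechanisms actively
restore, the way a thermostat defends its dial setting. The alternative is
that an individual's level is an *equilibrium point*: it simply falls where
the two arms of the negative-feedback loop intersect, with no target encoded
anywhere.

The two accounts are hard to separate within one individual — both predict
stable levels and compensatory hormone responses. They separate cleanly at
the population level. Write the loop as a *sensor* arm (hormone responds to
the parameter: PTH suppressed by calcium, insulin stimulated by glucose, TSH
suppressed by FT4) and an *effector* arm (parameter responds to the hormone:
calcium raised by PTH, glucose lowered by insulin, FT4 raised by TSH).

* Under set points, each individual's target must be attained by adjusting
  the controlling hormone — the effector arm is "slaved" to the target. An
  individual with a high target must run a correspondingly extreme hormone
  level, so across a cohort the parameter–hormone correlation must carry the
  sign of the **effector** direction: positive for calcium/PTH, negative for
  glucose/insulin.
* Under equilibrium points with interindividual variation concentrated in
  the effector arm, every individual sits on the shared sensor curve, so the
  cohort correlation carries the sign of the **sensor** direction — exactly
  the opposite sign in every negative-feedback loop.

Published cohort correlations therefore discriminate between the models.
The package bundles ten such correlations (five calcium/PTH subgroups from
two studies, five glucose/insulin subgroups from three studies); all ten
carry the sensor-direction sign, i.e. all are inconsistent with set-point
regulation and consistent with equilibrium-point regulation:

```{r table1}
evaluateTable(correlationFixture())
```

## The loop model

Curve shapes are a modelling choice — the discriminating prediction depends
only on monotonicity and direction, not on shape. We use:

* **Sensor** (parameter P to hormone H): log-linear,
  `H = exp(alpha + s * beta * P)` with slope sign `s` per direction and
  `beta > 0`. This guarantees a strictly positive hormone everywhere and is
  the conventional description of hormone responses measured on a log scale
  (the log-linear TSH–FT4 relationship being the canonical example).
* **Effector** (H to P): saturating hyperbola,
  `P = p0 + gain * H / (H + k)` (stimulatory) or
  `P = p0 + gain * k / (H + k)` (suppressive), so the physiological output
  is bounded in `[p0, p0 + gain]`. `p0` is the hormone-independent basal
  level, `gain` the maximal hormone-driven contribution, `k` the
  half-activation hormone level.

Both forms sit behind the `ResponseCurve` contract, so other monotone shapes
could be substituted without touching the rest of the machinery. Degenerate
curves (`beta = 0`, `gain = 0`) are rejected at construction: strict
monotonicity is what makes everything downstream well-posed. Units are
abstract throughout — the predefined `calcium_pth`, `glucose_insulin` and
`ft4_tsh` systems share illustrative magnitudes (`alpha = ±1`, `beta = 1`,
`p0 = 0.5`, `gain = 2`, `k = 1`) and differ only in their directions, which
are the physiological claims.

Because the directions are opposite, the composition `P -> g(f(P))` is
strictly decreasing, so `g(f(P)) - P` has exactly one sign change on the
bracket `[p0, p0 + gain]` and the equilibrium is unique. `solveEquilibrium()`
finds it by bisection on that bracket (no derivative needed, and bracketing
cannot escape), with a default residual tolerance of `1e-9` parameter units;
residual and iteration count are reported, not hidden. The bisection core is
vectorized over systems so a whole cohort is solved in one pass; tests check
it against a dense grid scan and against `uniroot()` as independent oracles.

```{r solve}
solveEquilibrium(predefinedSystem("calcium_pth"))
```

## The cohort simulators

`populationSpec()` describes a cohort: a template system, per-parameter
coefficients of variation, a model (`equilibrium` or `setpoint`) and a seed.
Design choices, made once:

* **Distribution family.** Curve parameters vary log-normally between
  individuals, median-preserving (`meanlog = log(template)`,
  `sdlog = sqrt(log(1 + CV^2))`): positive support, CV-parameterized, and a
  sample mean within `exp(sigma^2/2)` of the template. The sensor intercept
  `alpha` may be non-positive, so its CV acts on the multiplicative scale
  `exp(alpha)` — equivalently `alpha` receives additive Gaussian noise of
  the matching log-scale width.
* **Variation regime.** The default is `effector_dominant` (sensor CVs
  exactly zero, effector CVs 0.2): homeostasis is best served by tightly
  restricted variation in the hormone's response to the parameter, and this
  is the regime that turns the observed correlation signs into a sharp
  prediction. `sensor_dominant` and `mixed` are available for exploring the
  continuum; as the sensor CV shrinks the cohort correlation approaches the
  effector-dominant value (tested on a CV grid).
* **Set-point controller.** Modelled as exact attainment: each individual
  draws a target `T` (normal, CV 0.1 by default, centred on the template
  system's own equilibrium), independently of every effector draw — the
  independence *is* the set-point premise, targets chosen "without regard
  to" effector sensitivity. The hormone is then the closed-form inverse of
  that individual's effector curve at `T`. No dynamic controller is needed
  because only steady states are compared.
* **Truncation.** Targets are confined to
  `(p0 + 0.05 * gain, p0 + 0.95 * gain)` per individual (margin
  `epsilon = 0.05`) so the inversion stays well-conditioned; out-of-band
  draws are redrawn, at most 100 rounds before erroring.
* **Reproducibility.** One seeded generator per cohort; the seed travels in
  the `CohortSample` provenance and two runs with the same spec are
  bitwise identical.

```{r cohorts}
eq <- simulateEquilibriumCohort(
  populationSpec(predefinedSystem("calcium_pth"), n = 1000, seed = 1))
cohortCorrelation(eq, "spearman")$r   # exactly -1: all points on one sensor curve

sp <- simulateSetpointCohort(
  populationSpec(predefinedSystem("calcium_pth"), n = 1000, seed = 1,
                 model = "setpoint"))
cohortCorrelation(sp)$r               # positive: the set-point signature
```

What the generator deliberately does **not** emulate: assay/measurement
error on P and H, within-individual longitudinal variation, non-steady
(pulsatile) systems such as cortisol/ACTH or LH/testosterone, and any
estimation of curve parameters from real cohorts. Passing tests therefore
show that the *sign logic* of the two models is implemented correctly and is
robust across seeds and CV ranges — they are not magnitude claims about the
published cohorts, whose coefficients enter only as fixture inputs.

## Classifying published correlations

`impliedSign()` encodes the sign rules above; `classifyRecords()` compares a
record's coefficient sign with the model-implied sign
(`consistent` / `inconsistent`; exactly zero is `indeterminate`, never
coerced). Significance labels are carried through but never alter
classification — the bundled table keeps its two non-significant rows in the
count of ten, judged like the rest by point-estimate sign. The fixture
records each cohort's size, coefficient, method (`pearson` only where the
source prints it) and hormone transform (two studies correlate against log
insulin; a monotone transform does not affect the sign logic).

## The heating analogy

To show that target-free regulation is mechanistically ordinary, the package
implements a house heated by a four-element radiator with **no thermostat**:
elements switch on below 22, 20, 18 and 16 °C (strictly below — at the
threshold an element is off; the narrative implies no hysteresis, so
activation is a pure function of current temperature). Heat balance solves
`power * activeElements(T) = k (T - T_ext)`:

* crossing inside a constant step → a fixed point (e.g. `k = 0.5` kW/°C,
  `T_ext = 10` °C: stable at 16 °C on three elements, 3 kW);
* crossing at a step discontinuity → the temperature pins to the threshold
  and that element duty-cycles; the reported energy is the loss at the
  threshold, which is the time-averaged heater output there. This convention
  gives a well-defined energy at the discontinuity and is flagged by the
  `mode` field.

The thermostat comparison deploys whatever power holds its set point, capped
at the same 4-element total; past the cap it saturates at
`T_ext + 4 * power / k`. With no cooling circuit, a set point below ambient
is reported as ambient temperature at zero energy. `simulateDynamics()`
integrates `C dT/dt = heating(T) - k (T - T_ext)` by forward Euler
(defaults `C = 2` kWh/°C, `dt = 0.01` h, with the explicit-stability bound
`dt < C/k` enforced); duty-cycled steady states appear as small oscillations
around the threshold, and the tail-averaged temperature agrees with the
closed-form steady state. The thermostat's dynamic controller is
feed-forward demand plus a proportional term, clamped to the cap — the
simplest controller whose unsaturated stationary point is exactly the set
point.

The **two-towns experiment** then mirrors the cohort argument in thermal
form. Both towns share the climate (`T_ext = 10` °C), the heater hardware
(four 1 kW elements) and the spread of heat-loss coefficients
(log-normal, mean 0.2 kW/°C, CV 0.3 — placing houses across the interesting
16–22 °C band); one town is thermostat-controlled with set points drawn
independently of heat loss (normal, mean 21 °C, CV 0.05), the other runs the
threshold radiators. Across houses, the thermostat town shows a positive
temperature–energy correlation (aiming higher costs more) and the radiator
town a negative one (leakier houses run colder *and* burn more, because more
elements cut in) — the same sign reversal the endocrine cohorts show. All
magnitudes here are illustrative; only the correlation signs are claims.

```{r towns}
tt <- twoTowns(townSpec(nHouses = 500, seed = 1))
round(tt$correlations, 3)
```

## Numerical choices, sizes and limitations

* Solver: bisection to residual `1e-9` (≤ 200 iterations; ~45 in practice).
  Grid-scan oracles in the tests use 2,001–100,001 points with agreement
  required within two grid steps.
* Test problem sizes: sign-theorem suites run 200 seeded replicates at
  n = 1000 per system; the two-towns contract runs 100 replicates at 500
  houses per town; solver/oracle equivalence covers 1,000 random systems and
  100 random houses. These sizes make the stochastic checks sharp (binomial
  noise well below the 95% thresholds) while keeping the default test run in
  tens of seconds.
* The correlation machinery delegates to `stats::cor.test` (Pearson p-values
  via the t transform with n − 2 df; Spearman via the large-sample
  approximation, ties allowed).
* Known limitations: single-loop, two-arm systems only (no TRH–TSH–FT4
  three-tier cascade); steady states only, so spiking axes are out of scope;
  no unit conversions; the published coefficients cannot be recomputed from
  raw data (none are printed), so they are inputs, not outputs, of every
  analysis here.
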