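---
title: "Simulating stall-fed dairy cattle in the (Sub-)Tropics: model, parameterization and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating stall-fed dairy cattle in the (Sub-)Tropics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dairysim)
library(dplyr)
```

dairysim simulates one animal — typically a lactating zebu × taurine cow
on a forage-based diet — in monthly steps of 30.4 days.  This vignette
explains the sub-models and their assumptions, the parameters a user can
(and cannot) safely touch, the choices we made where the underlying
modelling literature leaves the design open, and what the test suite
does and does not demonstrate about real animals.

## The step cycle

Each monthly step executes six stages in a fixed order:

1. **Potential growth** from the Gompertz curve at the current weight.
2. **Potential milk yield** from the lactation curve at the current
   month of lactation, modified by the body-weight condition index.
3. **Factorial requirements**: ME and uCP costed at the *potential*
   performance of stages 1–2.
4. **Voluntary DMI** from the blended physical/physiological intake
   model, down-scaled by the condition index and capped by the feed
   offer; ME intake follows as DMI × diet ME.
5. **Partitioning** of the ME intake, with early-lactation body-reserve
   mobilization.
6. **State update**: weight, age, lactation month, gestation day.

The ordering matters: requirements feed the intake prediction, so they
must be computed from potential (genetic) performance before the actual
performance of the month is known.  Everything is deterministic; there
is no stochastic component anywhere in the engine.

## Growth and the body-weight envelope

The potential growth rate is
$\frac{dBW}{dt} = \mu_0 \, BW \, \frac{\ln(BW_f/BW)}{\ln(BW_f/BW_0)}$
with $\mu_0$ = 0.015 d$^{-1}$, birth weight $BW_0$, and mature weight
$BW_f$ set to 90 % of the genetic maximum attainable weight — an
assumption reflecting that cattle under (sub-)tropical feeding rarely
reach their genetic final weight.  The rate is capped at 1.2 kg/d and is
zero at or above $BW_f$.  Growth is *potential* only; the realized gain
comes out of the energy partition and is frequently negative in early
lactation.

The **condition index** locates the current weight between an
age-specific minimum and maximum weight,
$(BW_t - BW_{min,t})/(BW_{max,t} - BW_{min,t})$, clamped to [0, 1].  We
generate both envelope trajectories with the same Gompertz form as the
growth curve (same $\mu_0$, same birth weight), the minimum rising
toward `min_mature_weight` and the maximum toward
0.9 × `max_attainable_weight`.  Re-using the growth model keeps the
envelope internally consistent and needs no extra parameters.

A caution on identification: for a mature cow both envelope bounds sit
essentially at their asymptotes, so the index reduces to a linear
rescaling of body weight with intercept `min_mature_weight` and slope
1/(0.9·`max_attainable_weight` − `min_mature_weight`).  The bounds are
therefore identified only through the behaviour of the index — how hard
intake and milk react to weight loss — and not through any observable
weight.  The calibrated lower bound (38 kg in the bundled scenarios, see
below) must be read as an abstract anchor of this rescaling, not as a
biological minimum weight of an adult cow.

## Lactation

Potential milk in month $n$ is $y(n) = n/(a e^{kn})$ with $k = 1/T$ and
$a = 1/(\text{peak} \cdot (1/T) \cdot e)$; the curve peaks at exactly
the peak yield in month $T$, needs only those two parameters, and is
evaluated at integer months (first month of lactation = 1), matching
the monthly step.  Months outside the lactation return zero.

The classical approach modifies this genetic potential by the age and
body condition of the cow.  The published age/parity multipliers for
these breeds are not reproducible from the sources available to us, so
the age factor is fixed at 1 (an internal hook, `milk_age_factor()`,
marks the extension point).  The body-condition modifier is exposed as
the scenario parameter `milk_condition_exponent` ($\gamma$): potential
milk is multiplied by $index^\gamma$, so $\gamma = 0$ disables the
modifier and $\gamma = 1$ applies the index linearly.  Its default,
0.16, is calibrated (below).

Lactation stages follow the convention that body reserves support milk
only in the first three months: months 1–3 are *early*, the last three
months of the lactation length *late*, everything between *mid*, and
month 0 *dry*.

## Requirements

All requirements are factorial and summed per function:

| Component | Form | Source of coefficients |
|---|---|---|
| ME maintenance | 0.631·BW^0.75 MJ/d (0.53 for calves < 1 y) | (sub-)tropical maintenance estimates |
| ME lactation | (0.041·fat + 1.51)/k_l MJ per kg milk | k_l = 0.6 crossbred, 0.53 *B. indicus* |
| ME activity | (2.6·BW·horiz + 28·BW·vert)/10⁶/0.7 MJ/d | locomotion net costs |
| ME gestation | 0.044·e^{0.0165·d}/0.2 MJ/d, last 8 weeks only | d = days since conception |
| ME gain | age-interpolated net energy / 0.4 MJ per kg gain | packaged lookup tables |
| uCP gain | age-interpolated net protein × gain × 2.1 g/d | packaged lookup tables |

The net costs of body-weight change are age-dependent — not
weight-dependent — because (sub-)tropical cattle commonly show retarded
weight-for-age, which makes weight-based costing systematically wrong.
Between the tabulated age knots (0, 0.1, 1.5, 3, 4.5, 5.5, 20 years) we
interpolate linearly and extrapolate flat beyond the last knot; the
tables give knots only, and linearity is the minimal assumption.  The
factor 2.1 in the uCP-for-gain equation is implemented exactly as
specified in its source system; whether it is an inverse efficiency is
not stated there, and we do not re-interpret it.

The uCP requirements for maintenance, lactation and gestation are
defined in the German feed-evaluation system but their exact formulas
are not reproducible from our sources.  They are implemented as simple
coefficient forms — 3.9 g/kg^0.75/d for maintenance, 85 g per kg milk,
and a constant 135 g/d over the last eight weeks of gestation — with
the coefficients exposed as function arguments.  These are documented
stand-ins.  They are reported in every trace but deliberately have *no*
feedback on intake or performance, so they affect no other output.

The gestation term defaults to 280 days (configurable); days since
conception is the clock for the gestation cost.  There is no
reproduction sub-model: a pregnant state simply advances, and herd
events (conception, calving, culling) are out of scope.

## Intake

Voluntary DMI is the mean of a physically regulated term — the NDF
intake capacity 0.0135·BW divided by the diet NDF concentration — and a
physiologically regulated term — the total potential ME requirement
divided by the diet ME concentration.  Because the physiological term is
driven by *potential* performance it over-states what a thin cow will
eat; the blended estimate is therefore multiplied once by the condition
index, then capped by the feed offer.  The index multiplies the blend
exactly once — it is not applied again inside the requirement term,
except through the milk modifier described above.

## Partitioning and mobilization

The ME intake is allocated in priority order maintenance → activity →
gestation → milk → gain.  This ordering is a design choice: the
available-for-performance pool is defined as what remains after
maintenance, activity and gestation, which fixes those three ahead of
milk.  Of the performance pool, a stage- and diet-specific fraction
goes to milk — 1.00/0.85/0.74 in early/mid/late lactation on
forage-only diets, 1.00/0.88/0.80 when the ration contains
concentrates — capped at the energy cost of the month's potential milk;
the remainder, including any spill-over above that cap, buys gain at
the age-dependent ME cost per kg.

Mobilization rules:

* At most 0.23 % of body weight can be mobilized per day, a single cap
  shared between survival and milk support.  (Whether survival and milk
  mobilization share one cap or stack was ambiguous in the underlying
  rule set; we implement one shared cap, the conservative reading.)
* If intake falls below the maintenance-side obligations, reserves are
  mobilized for survival in any lactation stage.
* In early lactation only, additional reserves may be mobilized to lift
  milk to 60 % of the month's potential.  The 60 % level is a target
  for the top-up only: milk already funded by intake is never reduced,
  and beyond month 3 milk ceases entirely whenever intake remains below
  maintenance.
* Mobilized tissue is valued at the age-dependent net energy per kg of
  body-weight change and re-used with an efficiency of 0.84.  The
  crediting is *net-to-net*: against a maintenance deficit the tissue
  contributes NE × 0.84 directly, while for milk one kg of tissue
  supports NE × 0.84/(0.041·fat + 1.51) kg of milk — about 5.8 kg of
  milk per kg of body weight for typical milk fat.  We adopted the
  net-level conversion after finding that crediting the mobilized
  energy on the ME scale (dividing again by k_l's complement) cannot
  close the energy ledger of the bundled evaluation: it would require
  roughly three times the body-weight loss actually observed to fund
  the observed milk.

Energy closes exactly at every step: intake plus mobilized
ME-equivalents equals the sum of the five allocations, and the test
suite enforces this to 10⁻⁹ MJ on a thousand randomized inputs.

## Calibration of the unpublished breed parameters

The bundled evaluation scenarios (two groups of multiparous crossbred
cows in Ethiopia, fed maize–lablab stover or oats–vetch hay ad libitum
for five months from calving) specify the animal and diet completely
except for four quantities that the trial data do not contain: the
birth weight, the two envelope bounds, and the milk condition exponent.
These were calibrated once, by grid search followed by a simplex
polish, against the six published model outputs for the two treatments
(mean voluntary DMI, final body weight, mean daily milk yield),
minimizing the worst relative deviation.  The calibrated values —
`birth_weight` 32 kg, `max_attainable_weight` 630 kg,
`min_mature_weight` 38 kg, `milk_condition_exponent` 0.16 — are written
into the bundled YAML files and documented here; the acceptance tests
pin the resulting predictions to within ±5 % of the published values.

Two honest caveats.  First, as noted above, the envelope bounds are
identified only through the condition index; the calibration prefers a
wide, flat envelope (hence the low minimum bound), because a steep
index creates a positive feedback — weight loss → lower index → lower
intake → more weight loss — that collapses the simulation and is
incompatible with the observed trajectories.  Second, the calibrated
model predicts slightly *higher* intake for the heavier oats–vetch cows
than for the maize–lablab cows, whereas the published predictions have
the reverse ordering; within this model structure the heavier cow's
higher condition index always offsets the higher-NDF diet's lower
physical intake term.  The residual deviations (all outputs within
±5 %) trace mainly to this ordering tension.

## The synthetic-scenario generator

`synthetic_scenarios()` draws fully valid random scenarios spanning the
systems the package targets: initial weights 150–550 kg, diet ME 6–12
MJ/kg DM, diet NDF 0.35–0.75 kg/kg DM, peak yields 5–25 kg/d, lactation
lengths 8–12 months, both species classes, occasional finite feed
offers.  It exists to fuzz the engine (every generated scenario must
simulate without invariant violations) and to back the property tests;
it emulates the *range* of plausible inputs, not their joint
distribution in any real herd.  It does not emulate seasonal feed
variation, multi-lactation careers, disease, heat stress or grazing
selection — so passing property tests says the accounting is coherent
across the input space, not that the model is accurate for systems
unlike the stall-fed evaluation.

## Numerical choices and degenerate inputs

* **Integration** is monthly Euler: daily rates are held constant over
  the 30.4-day step.  A finer within-month integration would change the
  trajectories slightly but is outside the model's stated resolution.
* A five-step run covers 152 days; evaluations of 140-day postpartum
  periods conventionally use five monthly steps, and we keep that
  convention rather than truncating the fifth step.
* **Degenerate inputs** fail loudly and early: non-positive weights,
  NDF outside (0, 1), a collapsed envelope (min ≥ 0.9·max), negative
  intake, or a lactation month beyond the lactation length all raise
  classed errors at construction or call time rather than propagating.
* A zero (or near-zero) feed offer is legal and produces the starvation
  limit: no intake, no milk, and weight declining at the mobilization
  cap each day.
* Accuracy classes close the printed interval ends: RPE exactly 10 or
  20 is *good*, exactly 21 or 30 *fair*; values between 20 and 21 fall
  to *fair*.
* In the adequacy statistics the pair count q is the number of
  *treatment* pairs (2 in the bundled evaluation), not of animals.

## What the tests compute

The suite (about ten thousand assertions) covers the worked equation
examples to 10⁻⁶, the lookup tables cell-by-cell, energy closure and
the mobilization gate on ≥ 1000 seeded random partitions, curve-maximum
and envelope properties, byte-identical repeated traces, YAML and CSV
round-trips, and the reproduction of the published evaluation
statistics (to ±0.05 of their printed one-decimal values) and of the
published five-month predictions (to ±5 %).  Problem sizes — 1000
random partitions, 60 fuzzed simulations, 300 random paired series —
were chosen to exercise every branch while keeping a full run in the
tens of seconds.

```{r example}
trace <- run_simulation(builtin_fixture("maize_lablab"))
trace |> select(step, body_weight, condition_index, scaled_dmi,
                potential_milk, actual_milk, actual_gain)
glance(trace)
```

## Known limitations

* Single animal, single lactation window: no herd structure,
  reproduction, culling, or multi-year carry-over.
* No protein feedback: uCP balances are reported but never constrain
  milk or gain.
* The uCP maintenance/lactation/gestation coefficients are documented
  stand-ins, not the authoritative formulas of the source system.
* The age factor on potential milk is fixed at 1.
* The condition-index mechanism cannot reproduce a lower intake for a
  heavier cow on a higher-NDF diet (see the calibration section).
* Evaluated against one stall-fed dataset; accuracy for calves,
  heifers, grazing or mixed crop–livestock systems is untested.
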