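---
title: "Measuring transpiration resistances of fruit and vegetables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transpiration resistances of fruit and vegetables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transpirest)
```

## The model

Fresh fruit and vegetables lose water continuously after harvest. The flux is
well described by a diffusion law in series-resistance form: the area-related
transpiration rate $E$ (mg cm$^{-2}$ h$^{-1}$) is the ratio of a water-vapour
concentration difference to a total transport resistance,

$$E \;=\; \frac{x_p - x_a}{r_T + r_B} \;=\; \frac{\Delta x}{r_{tot}},$$

where $x_p$ is the water-vapour concentration of the air in the intercellular
spaces of the produce, $x_a$ that of the ambient air at sufficient distance
from the surface (both in g m$^{-3}$), $r_T$ the tissue resistance of the
epidermis and flesh, and $r_B$ the boundary-layer resistance of the stagnant
air film at the surface (both in s cm$^{-1}$). The intercellular air is at, or
very near, saturation in fresh produce; its equilibrium relative humidity is
the tissue water activity $a_w$ (default 0.985 for fresh apples without
wilting signs). $E$ itself is measured non-destructively by differential
weighing: $E = \Delta FM / (A\,\Delta t)$ with a 0.1 mg precision balance and
a surface area $A$ estimated from an allometric regression.

With $\Delta x$ in g m$^{-3}$ (= µg cm$^{-3}$) and $E$ in mg cm$^{-2}$ h$^{-1}$
(= 1000/3600 µg cm$^{-2}$ s$^{-1}$), a resistance in s cm$^{-1}$ is
$r = 3.6\,\Delta x / E$. This factor is forced by the unit choices; it lives
in the single exported constant `FLUX_UNIT_FACTOR` and is checked by a test.

## Psychrometrics

Both concentration endpoints come from a chain of psychrometric relations:
saturation vapour pressure from temperature (an exponential-rational
approximation), partial pressure from relative humidity, mixing ratio from
partial and barometric pressure (gas-constant ratio 287.058/461.52 =
0.62198), humid-air density from the ideal-gas mixture, and finally the
volume-related water content $x^* = x\,\rho$ in g m$^{-3}$. Note that this
product multiplies a *dry-air-mass-based* mixing ratio by the *moist-air*
density; the result is an approximation to grams of water per cubic metre of
moist air. We follow the method's formula literally rather than "correcting"
it — the same convention is used forwards and backwards, so resistances and
recovered humidities are internally consistent.

The saturation-pressure approximation is accepted on $-10$ to $+50$ °C (the
postharvest range); outside it the function raises rather than extrapolate,
since the fit range of the underlying approximation is not documented. Against
standard steam-table values at 0–30 °C it agrees within 1 %.

The inverse problem — given a volume-related water content, find the relative
humidity — has no closed form because both the mixing ratio and the density
depend on the vapour pressure. `humidity_from_volume_content()` uses a
fixed-point iteration on the mixing ratio (relative tolerance $10^{-9}$, at
most 100 iterations; the contraction factor is about the mixing ratio itself,
so fewer than 10 iterations suffice in the valid domain). The forward/inverse
round trip is exact to well below $10^{-6}$ percentage points of rH.

## Surface area

Seven produce types carry calibrated regressions of surface area on fresh
mass and, where the shape demands it, on length and diameters (asparagus:
mass and length; carrot: mass, length and mean diameter; radish tuber: height
and transverse diameters, the latter measured twice with a 90° rotation and
averaged — the protocol states two measurements but not the reduction, and
the mean is the natural choice). Coefficients are shipped verbatim in a CSV
at full published precision. A mass outside the calibrated range evaluates
with a warning rather than failing: the regressions are empirical and no
extrapolation guidance exists, so the user decides. A measured area always
overrides the regression.

## Protocols and partitioning

`run_protocol()` turns one weighing series plus a climate log into a
`resistance_result`. The transpiration rate uses endpoint differencing of the
first and last weighings by default (the weight-loss-over-interval reading of
the procedure); a least-squares slope of mass against time is available for
noisy series. The ambient state uses the time-weighted mean of temperature
and relative humidity over the weighing interval, then a single psychrometric
evaluation — a small-fluctuation approximation that is exact for constant
climate and accurate when drift is slow relative to the interval. Four
partitioning protocols are supported:

* **free** convection: $r_B$ is assumed (4.0 s cm$^{-1}$ is accepted as a
  default for apples only; other species must supply a value or use a
  difference protocol) and $r_T = r_{tot} - r_B$;
* **forced** convection (airflow > 2 m s$^{-1}$) and **wetted** surface: the
  boundary layer is taken as stripped, $r_B = 0$, $r_T = r_{tot}$. No
  residual-$r_B$ correction is applied because none is available;
* **bulk**: fruit packed in a container; the individually measured $r_T$ is
  supplied and the (much larger) effective boundary-layer resistance is
  $r_B = r_{tot} - r_T$.

A negative $r_T$ or $r_B$ is always an error, never clamped: it indicates
inconsistent protocol or climate inputs, and hiding it would defeat the
method's purpose. The produce temperature is an input (infrared measurement
recommended); when absent, the mean air temperature is substituted and the
substitution is logged — the evaporative surface-temperature depression is
deliberately not modelled. Every assumption actually used (default boundary
layer, default barometric pressure of 101325 Pa, temperature fallback) is
messaged and recorded in the result's provenance, because the credibility of
the method rests on exposing its assumptions.

With $r_B$ known, the surface state follows from the flux across the boundary
layer alone, $x_{pS} = x_a + E\,r_B/3.6$, and the surface relative humidity
from the inverse psychrometric solve. The inverse is evaluated at the
produce temperature when one was supplied and at the air temperature
otherwise (the method does not specify the basis; the choice is flagged in
the provenance). Water activity is taken from the produce item when set,
falling back to the protocol configuration — so an item simulated with a
given $a_w$ inverts exactly under the default configuration.

Resistances are temperature dependent. `arrhenius_adjust()` applies
$r(T) = r_\mathrm{ref}\exp[(E_a/R)(1/T - 1/T_\mathrm{ref})]$ with absolute
temperatures; there is no universal activation energy, so $E_a$ must be
supplied or estimated from measurements at two or more temperatures
(`estimate_activation_energy()`, a least-squares Arrhenius fit). The bundled
reference table gives measured apple tissue resistances of 391 s cm$^{-1}$ at
20 °C and 750 s cm$^{-1}$ at 1 °C — a ratio of 1.92, corresponding to
$E_a \approx 22.9$ kJ mol$^{-1}$.

## The forward simulator

`forward_simulate()` runs the same diffusion model forwards to generate
synthetic weighing and climate logs with known resistances, which makes the
whole estimation chain testable without laboratory data. Design choices:

* **Integrator**: fixed-step explicit stepping at one-minute internal
  resolution. The dynamics are quasi-static (the mass-loss rate feeds back on
  nothing within a run), so nothing stiffer is warranted; with constant
  climate the integration is exact.
* **Surface area** is held at its initial value: protocol losses are well
  under 1 % of mass, matching the practice of measuring the area once in a
  preliminary test.
* **Balance quantisation**: sampled masses are rounded to the balance
  resolution, default 0.1 mg as for a precision balance. Set 0 to disable.
* **Climate drift**: optional stationary AR(1) perturbations of temperature
  and humidity at the minute scale, default off. The produce temperature does
  not follow the drift (thermal inertia); it is the item's measured value or
  the nominal air temperature.
* **Default conditions** mirror the validated apple study: 131 g apples
  (population 131 ± 20 g), 20 °C, 50 % rH, 101325 Pa, 24 h duration with 2 h
  weighings, $r_T = 391$, $r_B = 4.8$ s cm$^{-1}$ individually and
  $r_T = 363$, $r_B = 50.4$ s cm$^{-1}$ in bulk over 48 h.

`recovery_experiment()` closes the loop: simulate, estimate, report true
versus recovered resistances. On noiseless data all four protocols invert to
floating-point precision (relative error below $10^{-9}$; the difference
protocols simulate the paired free and stripped runs on the same fruit). With
0.1 mg quantisation, 2 h weighings and 24 h duration, the roughly 370 mg
daily loss of the reference apple dwarfs the ±0.1 mg endpoint error, so
single-run tissue-resistance errors stay far inside 5 % and the mean over 100
fruit drawn from the 131 ± 20 g population is within 1 % of truth. In the
test suite these experiments use that population draw as the across-run
variability, since quantisation of an identical trajectory is deterministic.

```{r recovery}
apple <- produce_item("demo", "apple", mass_g = 131)
spec <- simulation_spec(apple, r_T_s_cm = 391, r_B_s_cm = 4.8,
                        balance_resolution_mg = 0)
suppressMessages(recovery_experiment(spec, "free"))
```

## What the simulator does and does not emulate

The generator reproduces the measurement physics: psychrometrically driven
mass loss, balance quantisation, slow climate drift, the weighing cadence. It
does **not** emulate biological variability in $r_T$ between fruit, the
near-linear growth of tissue resistance during storage, respiration-driven
mass changes, heat-balance surface-temperature depression, or packaging-film
permeance beyond a constant series resistance. Passing recovery tests
therefore demonstrate the correctness of the estimation chain under the
model's assumptions, not the field accuracy of those assumptions on real
produce.

## Numerical and degenerate-input choices

Tolerances: $10^{-9}$ relative for the inverse-humidity fixed point;
supersaturation is tolerated to $1+10^{-9}$ relative before erroring, so
round-trips at exactly 100 % rH do not trip the guard. Weighing series need
at least two records and strictly increasing timestamps; constant-mass series
produce a no-transpiration error, mass-gaining series a condensation warning
(and an error once a resistance is requested, since the model does not cover
the condensation regime). Series shorter than the recommended duration (24 h
individual, 48 h bulk — the packaged-fruit procedure extends the interval to
2–3 days) warn but run. CSV readers reject missing columns, unparseable
timestamps, duplicate (item, timestamp) pairs, non-monotone time, negative
masses and out-of-range humidity with actionable messages; writers emit full
precision so numeric columns round-trip bit-identically.

## Problem sizes used in the test suite

Unit and property tests run on small grids (500-point inverse round-trip,
1000 random flux-continuity states, 100 simulated fruit at one-minute
integration over 24–48 h), which keeps the full suite under half a minute
while exercising every code path end to end.
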