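---
title: "The exercise-hormone model: assumptions, parameters, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The exercise-hormone model: assumptions, parameters, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exermet)
```

## The model

`exermet` simulates the counter-regulatory hormonal response to a single
session of sub-maximal aerobic exercise. Four coupled states evolve over a
session of minutes to hours:

* **Suprabasal oxygen uptake** `PVO2max(t)` (%VO2max) follows first-order
  step-response kinetics driven by the piecewise-constant prescribed
  intensity `u(t)`:
  `dPVO2max/dt = −r·PVO2max + r·u(t)`, with `r = 0.8 min⁻¹` by default so
  the target is reached in roughly 5–6 minutes. This single-exponential
  description is valid only below the lactate threshold; above it a slow
  second component appears that the model deliberately omits.

* **Epinephrine** `CE(t)` (pM) is secreted at a rate
  `(f1 + f2(Ca,g) + f3(PVO2max))·BW` (pmol/min), diluted into a volume of
  distribution `Vd`, and eliminated in first order. `f2` is a decreasing
  sigmoid in arterial glucose (hypoglycaemic counter-regulation, midpoint
  `c3`), `f3` an increasing sigmoid in relative intensity (midpoint `d3`).
  The elimination constant `k` is *derived*, not set: imposing zero change
  at the basal state (epinephrine `CE0`, fasting glucose 5 mmol/L, no
  exercise) gives `k = BW/(Vd·CE0)·(f1 + f2* + f3*)`.

* **Insulin and glucagon** `CI(t)`, `CG(t)` (pM) obey multiplicative
  proportional-control laws around their basal values; epinephrine enters
  the insulin equation through the coupling `k5` exactly as the glucagon
  and insulin self-terms do. The offset `h` is derived by imposing the
  basal fixed point at fasting glucose, `h = D/φ(5)`; when the modulation
  functions `φ` and `ψ` disagree there, no consistent calibration exists
  and the package raises an error rather than preferring one equation
  silently.

Arterial glucose is an *input*, not a state: the organ-level metabolic
network that would close that loop is out of scope, and the glucose
provider contract (constant, interpolated time series, or a clearly-marked
toy feedback loop) stands in for it. With the default constant 5 mmol/L,
`f2` contributes a constant basal term and all exercise dynamics flow
through `f3`.

## Parameters

Prescription-layer constants are the standard metabolic-equation
coefficients and are not tunable. The dynamic layer's tunables:

| parameter | default | units | meaning |
|---|---|---|---|
| `rate` | 0.8 | min⁻¹ | oxygen-uptake time constant (5–6 min rise) |
| `Vd` | 20 | L | epinephrine distribution volume |
| `f1` | 8 | pmol·kg⁻¹·min⁻¹ | basal epinephrine secretion |
| `c1, c2, c3` | 20, 1.5, 3 | pmol·kg⁻¹·min⁻¹, L·mmol⁻¹, mmol·L⁻¹ | glucose sigmoid |
| `d1, d2, d3` | 30, 0.1, 40 | pmol·kg⁻¹·min⁻¹, (%VO2max)⁻¹, %VO2max | exercise sigmoid |
| `CE0, CI0, CG0` | 200, 60, 28.7 | pM | basal epinephrine, insulin, glucagon |
| `k1, k2, k3, k4` | 2e-3, 1e-3, 1e-3, 1.4e-3 | pM⁻¹·min⁻¹ | controller gains |
| `k5` | 3.6e-5 | pM⁻¹·min⁻¹ | epinephrine→insulin coupling (published estimate) |
| `D` | 0.1 | min⁻¹ | controller degradation constant |

All hormone concentrations are carried in pM throughout, the unit in which
`k5` is denominated; unit coherence of the controller law was preferred
over mass-concentration conveniences.

Only `k5` and `D` have published values. The remaining constants were
inherited, in the work this package operationalizes, from earlier
whole-body models whose tables are not reproduced; the **reference
configuration** (`reference_parameters()`,
`inst/extdata/reference_config.json`) therefore carries values this package
chose and documents. They were selected once, on physiological grounds, so
that the resting state is plausible (basal epinephrine 200 pM, insulin
60 pM, glucagon 28.7 pM, derived epinephrine half-life ≈ 4 min) and a
60-min bout at 60 %VO2max produces excursions of the size the classical
validation study reports: epinephrine ≈ 3.7× basal, insulin ≈ −30%,
glucagon ≈ +25%, with both eigenvalues of the controller's basal Jacobian
real and negative (no hormone oscillations, recovery time constants of
roughly 8 and 35 min). Because the configuration is package-chosen, every
estimation claim in the test suite is *self-consistent*
(simulate-then-recover), valid under any positive configuration; only the
order of magnitude of the precision figure is comparable with the published
one.

The normative VO2max table (`inst/extdata/vo2max_norms.csv`) is likewise
external reference data — ACSM-style population values by gender, decadal
age bracket (20–89, clamped at the extremes) and five fitness categories —
and a measured VO2max always overrides it.

## The synthetic-data generator

`generate_observations()` emulates the measurement process of the
estimation design: insulin and glucagon sampled every 10 min from 30 min
before to 180 min after exercise onset (`estimation_schedule()`; the
original study's exact schedule is not printed), each observation perturbed
multiplicatively with a constant 4% coefficient of variation — the error
model assumed for the published fit — and re-drawn if non-positive. It
does *not* emulate: between-subject variability (observations are noisy
copies of one trajectory, whereas the published fit used means over 13
subjects), assay drift or correlated errors, sampling-time jitter, or any
model misspecification. Passing recovery tests therefore demonstrate
identifiability and correctness of the estimation machinery under the
model's own assumptions, not robustness to real-data pathologies.

## Numerical choices

* **Integration.** `deSolve::ode` (lsoda, stiff-capable, adaptive) at
  `rel_tol = 1e-8`, `abs_tol = 1e-10`. Segment boundaries are mandatory
  restart points, so the discontinuous input never straddles a solver
  step; the output grid only selects reporting times and does not affect
  the dynamics.
* **Analytic oracle.** The oxygen-kinetics equation has an exact
  piecewise-exponential solution (`pvo2max_closed_form()`), used to verify
  the integrator to < 1e-6 %VO2max.
* **Sigmoids** are evaluated with a sign-branched logistic so extreme
  arguments saturate gracefully instead of overflowing; in double
  precision the strict bounds `0 < f < amplitude` hold only while the
  argument magnitude stays below ≈ 36.
* **Fitting.** `minpack.lm::nls.lm` (Levenberg–Marquardt) on the
  CV-weighted residual vector (insulin block then glucagon block, equal
  per-point weighting after CV scaling), bounds `k5 ≥ 0`. Weights use
  *observed* values in the denominator (the measurement-CV convention);
  model-predicted weighting is available as an option.
* **Precision.** The residual Jacobian is computed by forward finite
  differences with relative step 1e-6 (centred differences as a
  verification mode); `CV% = 100·sqrt(diag((JᵀJ)⁻¹))/|estimate|`. The
  ×100 convention is used: a "percent" figure in low single digits is only
  consistent with it. A rank-deficient Jacobian raises an identifiability
  error naming the parameter.
* **Degenerate inputs.** Empty protocols simulate to the constant basal
  state; a zero-length sweep or singleton sweep reduces to a plain
  simulation; ages outside 20–40 years warn (outside the validated range)
  and outside 10–100 error.

## Design decisions

* The session energy-equivalent work-rate figure for gait modalities
  multiplies by session duration exactly as conventionally printed
  (`vo2 · BW · duration · 5e-3 · 1.163`), which yields an energy-like
  quantity despite its Watt label; it is implemented as printed and
  documented as a per-session surrogate.
* Resting oxygen uptake defaults to 3.5 ml·kg⁻¹·min⁻¹ (1 MET).
* The incremental validation study (fixture 1) is encoded with four 8-min
  bouts per the tabulated design; the narrative 7-min variant is available
  via `segment_minutes = 7`. Its intensity sequence 38/51/64/77 %VO2max is
  stored directly (the maximal-work-capacity conversion behind it is not
  printed), and the final bout is tagged `above_lt`, triggering a validity
  warning when simulated.
* Fixture 6's muscle-glycogen observable needs an organ-level model and is
  marked unsupported; heights are stored but unused (no equation consumes
  them).
* Simulations always start from the basal state at `t0`; protocols place
  exercise onset via their segment start times (the estimation design uses
  onset at minute 30 to reproduce its 30-min baseline).

## Problem sizes

The packaged analyses are desk-scale by design: trajectories of 200–400
output points over 2–4 simulated hours, estimation designs of 22 sampling
times × 2 hormones = 44 observations, and Monte-Carlo recovery studies of
12–20 noise replicates. A single simulation takes ~0.1 s and a full fit
~1 s on commodity hardware.

## Limitations

* Valid below the lactate threshold only; no slow VO2 component, no
  above-threshold metabolism.
* Arterial glucose is exogenous unless the toy feedback provider is used,
  and that provider is a qualitative stand-in, not a validated model.
* Cortisol, growth hormone and other counter-regulatory signals are not
  modelled; neither are organ-level fluxes (hepatic glucose production,
  muscle glycogen).
* The normative VO2max table and the auxiliary hormone constants are
  reference/package-chosen values, not study-derived; conclusions that
  depend on their absolute magnitudes (rather than on self-consistent
  recovery) should be drawn with care.
* Heart-rate-based intensity anchors (%HRmax, heart-rate reserve) are not
  implemented; intensity is %VO2max throughout.
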