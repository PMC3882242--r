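---
title: "Modelling cortical spreading depression with a modulated refractory period"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cortical spreading depression with a modulated refractory period}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csdwave)
```

## The model

Cortical spreading depression (CSD) is a slowly propagating wave of ionic
disturbance in the cortex, tracked here through the extracellular potassium
level.  `csdwave` treats the cortex as a 2D excitable sheet with two state
variables per grid element: the potassium level $K$ and a lumped recovery
variable $R$ that stands for the restoration of ionic homeostasis after a
wave (sodium-potassium pump activity and related processes).  The dynamics
are

$$\frac{\partial K}{\partial t} = D\,\Delta K + f(K, R), \qquad
  \frac{dR}{dt} = E\,(K - K_{rest}) - C\,(R - R_{rest}),$$

with the bistable reaction term (kinetics form `"default_cubic"`)

$$f(K, R) = (K - K_{rest})\,\bigl[A\,(K - K_\theta)(K - K_{max})
            - B\,(R - R_{rest})\bigr].$$

With $R$ frozen at rest, $f$ is a bistable cubic: the rest state
$K_{rest}$ and the excited state $K_{max}$ are separated by the threshold
$K_\theta$, so a suprathreshold potassium elevation triggers a
self-propagating front.  As $K$ stays elevated, $R$ grows; a large $R$
first erodes and then (beyond a fold at $R \approx 1.22$ under the default
constants) abolishes the excited branch, which terminates the pulse and
leaves a refractory tail that relaxes at rate $C$.  Elevated $R$ opposes
re-excitation, so $R$ is the model's expression of the refractory period.

All variables are dimensionless and on relative scales.  The default
constants are $A=-0.54$, $B=0.12$, $C=0.018$, $D=0.005$, $E=0.03$,
$K_{rest}=0.03$, $K_\theta=0.2$, $K_{max}=1$, $R_{rest}=0.5$ (see
`csd_params()`).

### Refractory-period modulation

A rectangular *modulated area* of the grid slows its own recovery: inside
it, $dR/dt$ is multiplied by a factor $F \in (0, 1]$ whenever $dR/dt < 0$.
Growth of $R$ is never modulated, so the fastest recovery rate matches the
control area, and $F = 1$ reproduces the control dynamics bit for bit.
$F = 0$ is excluded: modulation is multiplicative on a negative rate, and
$F = 0$ would freeze recovery forever rather than slow it.

### Why the kinetics are a documented reconstruction

The model is assembled from a published constant table whose two recovery
rate constants (0.018 and 0.03) are labelled identically, and whose
equations we could not transcribe literally.  The package therefore treats
the kinetics as pluggable forms (`kinetics_form()`) constrained by
structural contracts — rest is a fixed point, excitation is bistable about
$K_\theta$, recovery grows with $K$ and relaxes toward $R_{rest}$ — and
ships the reconstruction above as the default.  Two choices deserve
explicit justification:

* **Rate-role assignment.**  With the growth coefficient 0.018 and
  relaxation 0.03, the local $(K, R)$ system has a second stable fixed
  point on the excited branch ($K \approx 0.8$, $R \approx 1.0$): pulses
  never terminate, the tissue depolarises permanently, and no successive
  waves are possible.  With growth 0.03 and relaxation 0.018 the
  $R$-nullcline crosses the fold and the medium is properly excitable.
  The package assigns the letters so that parameter *values* match the
  published table ($C = 0.018$, $E = 0.03$) while the *roles* make the
  medium excitable: $E$ couples potassium into $R$-growth, $C$ relaxes it.
* **Recovery coupling in $f$.**  The coupling enters multiplied by
  $(K - K_{rest})$, so the resting state is a fixed point for *any*
  recovery level: baselines stay flat between waves and $K$ never
  undershoots its resting value.  The additive (FitzHugh–Nagumo-style)
  variant is also shipped as `"additive_cubic"`; under the published
  constants it leaves a marginally stable depolarised state and is not
  used by the presets.

## Numerics

Integration is the canonical explicit scheme: a 5-point Laplacian with
zero-flux (mirror-ghost) boundaries and forward Euler in time.  Defaults:

* **Grid**: $80 \times 80$ elements.
* **Grid spacing** `dx = 0.25` length units.  The bistable front width is
  $\sqrt{2D/|A|}/(K_{max}-K_{rest}) \approx 0.14$ units.  At `dx = 1` the
  front is far below the lattice resolution: the discrete front creeps at
  a quarter of the continuum speed and the excited core recovers before
  the front crosses a single cell, so *no wave exists at all*.  At
  `dx = 0.25` (domain $20 \times 20$ units) the full phenomenology —
  ring waves crossing the whole grid, recovery, bypass, slowdown,
  re-entry — is reproduced.  Both `dx` and the grid shape are
  configurable, and a coarsened $40 \times 40$ grid preserves the regime
  ordering.
* **Time step** `dt = 0.05`.  The diffusion stability bound is
  $dx^2/(4D) = 3.125$, checked by `check_stability()` and enforced at
  construction; accuracy of the stiff reaction term is the practical
  constraint.  Halving `dt` moves wave onset times by well under 1%
  (first-order convergence is asserted in the tests).
* **Blow-up detection** every step: any non-finite field value aborts with
  the offending step index rather than clamping, so parameter misuse is
  loud.
* **Determinism**: there is no randomness anywhere; rerunning a scenario
  (or its serialized config) reproduces every output bit-identically.

The plain-R stepper `csd_step()` defines the scheme; `csd_simulate()`
drives an identical compiled loop for the shipped kinetics (tests assert
bitwise agreement) and falls back to the R stepper for user-registered
forms.

## The in-silico experiments

`make_scenario()` builds the five preset experiments.  They share a
protocol whose layout follows the published schematic — a central
suprathreshold stimulus, a rectangular modulated area in the upper-right
quadrant, and two probes at exactly equal distance from the stimulus site
(the control probe is the point reflection of the modulated probe through
the grid centre, which also makes the $F = 1$ run exactly symmetric) —
while the unpublished constants are this package's own, chosen as follows
and fixed once:

* **Stimulus**: potassium clamped to $K_{max}$ on a disk of radius 3 cells
  for 10 time units.  Wave properties far from the source are insensitive
  to these details (asserted as a property test).
* **Modulated area**: a $12 \times 12$-cell rectangle (rows 15–26,
  columns 55–66).  The area must be shallow enough that waves entering
  partially recovered tissue can reach the probe before the pulse's own
  wave-back extinguishes them; with a much deeper area the slowed regime
  collapses into the blocked one and the intermediate-$F$ phenomenology
  disappears.
* **Inter-stimulus interval**: 1000 time units.  The control area
  recovers within about 360 time units of a wave's passage, so the
  interval must exceed that; its exact value is the one protocol constant
  the published $F$-interval boundaries depend on.  It was calibrated so
  that the two canonical experiments land in their published regimes
  (bypass at $F = 0.05$, slowdown at $F = 0.25$), which places the
  blocked/slowed transition of the $F$ sweep at 0.09/0.10.  This is the
  only constant tuned against a published number; everything downstream
  (the three-wave sequence, monotone speeds, re-entry) must emerge
  unaided.
* **Slowdown margin** $\delta = 1$ time unit (ten recording intervals at
  the default stride): onset delays above it are classified `"slowed"`,
  separating genuine slowdown from numerical jitter.

The `three_waves` preset adds a third stimulus 1500 time units after the
second: long enough for the modulated area at $F = 0.05$ to recover
partially, so the third wave enters it slowly after the second was
blocked.

### The re-entry (spiral) protocol

In the reconstructed kinetics the medium is *subexcitable*: a broken
wavefront's free ends always retract, so the free ends left by releasing a
linear conduction block curl nowhere — they shrink and die (we verified
this across block geometries, timings and release schedules).  Functional
spiral formation by free-end curling is therefore dynamically unavailable
in this parameter regime.

Re-entry — self-sustained activity with more wave events at a probe than
stimuli delivered, `detect_reentry()` — is instead produced the way
low-excitability media support it: as a **rotating wave anchored to a
transient anodal block**.  The `spiral` preset seals a central disk of
tissue with an insulated block (`block_event(mode = "insulate")`: cells
frozen *and* walled off by internal zero-flux faces, i.e. no ionic current
through the blocked tissue), turning the cortex into an annular corridor.
A corridor stimulus plus a brief one-way gate (a second insulated block,
released after the wave's tail has passed) launches a unidirectional wave
that circulates around the obstacle with a lap time of roughly 1900 time
units, re-exciting every corridor site each lap.  The default `freeze`
block mode (cells held at their current values but still diffusively
coupled) remains available and is what a refractory — rather than sealed —
tissue segment corresponds to.

## Measurement layer

* `detect_wave_events()` — one event per contiguous suprathreshold
  ($K > K_\theta$) excursion of a probe trace, crossing times linearly
  interpolated.
* `classify_regime()` — pairs control and modulated events by order within
  a matching window (one inter-stimulus interval) and labels each wave
  `blocked`, `slowed`, or `homogeneous`.
* `propagation_speed()` — least-squares slope of the farthest
  suprathreshold cell along a ray against time; the front position is
  threshold-based for consistency with the $K_\theta$ semantics (a
  half-maximum definition was rejected for that reason).
* `sweep_F()` — reruns the two-wave protocol across an $F$ grid and
  reports the regime table and the blocked/slowed boundaries.

## What the presets do and do not show

The presets are the package's synthetic experiments: they emulate the
idealised study conditions — a homogeneous isotropic sheet, a clean
potassium clamp, a perfectly rectangular modulated area — not real
cortical recordings.  Passing tests demonstrate that the *mechanism*
(slowed recovery lengthens the refractory period, which blocks or slows
subsequent waves and supports anchored re-entry after block release) is
reproduced, with regime boundaries that depend on the documented protocol
constants.  They do not show anything about cortical geometry, vascular
heterogeneity, multi-ion dynamics, or osmotic effects, all of which are
outside this model by construction.

## Known limitations

* The kinetics are a contract-constrained reconstruction; absolute wave
  speeds and the precise $F$ boundaries inherit that uncertainty, and the
  published boundary values are matched only under the documented default
  protocol.
* The medium is subexcitable, so free-end curling (figure-of-eight spiral
  pairs) does not occur; re-entry requires an anchoring obstacle.
* Forward Euler is first-order: probe onset times carry an $O(dt)$ bias
  (below 1% at the default `dt`).
* The $K$-field invariant $K \in [K_{rest}, K_{max}]$ is monitored, not
  clamped; stimuli and kinetics outside the documented ranges can and
  will blow up, by design loudly.

## A worked run

```{r example, eval = FALSE}
run <- csd_simulate(make_scenario("bypass", F = 0.05))
classify_regime(run)
autoplot(run)

sw <- sweep_F("bypass", seq(0.05, 0.15, 0.01))
sweep_boundaries(sw)
```
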