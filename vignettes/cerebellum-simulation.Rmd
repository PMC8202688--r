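---
title: "Simulating the cerebellar microcircuit with reference and fixed-point arithmetic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the cerebellar microcircuit with reference and fixed-point arithmetic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science and the engineering decisions inside
`cerebsim`: the neuron and synapse model, the synthetic wiring generator and
what it can and cannot stand in for, the fixed-point emulation, the analysis
pipeline, and the communication-load model. It also records where the
package's results depart from their published reference values and why.

## The circuit

The model is a 400 × 400 × 900 μm block of mouse cerebellar cortex plus its
deep-nucleus target: 96,737 cells in seven populations and 4,214,215
synapses in sixteen projections, all encoded verbatim in
`canonical_model()`. Glomeruli (`Glom`, 7,073) are relay "cells": they emit
prescribed spike trains and have no membrane dynamics. Granule cells
(`GrC`, 88,158 — 91% of all cells) excite Golgi (`GoC`), stellate (`SC`),
basket (`BC`) and Purkinje (`PC`) cells through ascending-axon (`aa-`) and
parallel-fibre (`pf-`) projections; 86% of all synapses originate at GrC.
Purkinje cells receive the extreme fan-in (28,665 synapses on average,
28,375 of them parallel fibres) and inhibit the twelve deep-nucleus cells
(`DCNC`), which are tonically active and pause when Purkinje activity
bursts.

## Neuron model and solver

All non-relay cells are conductance-based leaky integrate-and-fire neurons
with exponential synaptic conductances. Working with the normalized
conductance `ĝ = g·tau_m/Cm` (dimensionless) and normalized offset current
`î = i_offset·tau_m/Cm` (mV), the sub-threshold dynamics over an interval
`h` with `ĝ` frozen have the exact solution

```
v_inf  = (v_rest + ĝ_e E_e + ĝ_i E_i + î) / (1 + ĝ_e + ĝ_i)
v(t+h) = v_inf + (v(t) − v_inf) · exp(−h (1 + ĝ_e + ĝ_i)/tau_m)
```

The engine advances each timestep `dt` (default 0.1 ms) in `n_sc`
sub-cycles of length `h = dt/n_sc`; each sub-cycle first decays both
conductances by their exact factors `exp(−h/tau_syn)` and then applies the
membrane propagator. Threshold crossing, reset and the refractory clamp are
resolved once per full timestep, so spikes exist at `dt` resolution only.

Decisions worth recording:

* **`n_sc = 2` by default.** The sub-cycle count is a tunable accuracy knob
  that is not fixed by the model itself; two sub-cycles is the smallest
  value that exercises the mechanism, and the test suite checks the solution
  against an adaptive continuous-time integration (deSolve, `rtol = 1e-10`)
  under a strong fast-synapse transient: the default tracks the reference to
  a few percent of the transient's depth, and refining `n_sc` reduces the
  error further.
* **Operation order.** Within a sub-cycle the conductance decays before the
  membrane update, i.e. the membrane sees the end-of-interval conductance.
  The alternative order (membrane first) was measured and changes
  refractory-limited firing rates by ~2.5%; neither order is privileged by
  the frozen-conductance assumption, so the package fixes the first and
  documents it.
* **Refractoriness.** `round(tau_refract/dt)` timesteps (ties round up);
  the membrane is clamped at `v_reset` while conductances continue to decay
  and accumulate. A refractory period of 1.5 ms at `dt = 0.1` is exactly 15
  clamped steps, verified in the tests.
* **Input timing.** Synaptic increments scheduled for step `t` are added
  before the first sub-cycle of `t`. A spike with delay `d` emitted at step
  `s` first affects its target at step `s + round(d/dt)`; all printed delays
  are integral multiples of `dt`, so the rounding is exact. Delays live in a
  64-slot ring buffer (at most 6.4 ms; construction fails beyond that).

## Fixed-point back-end

The `fixed` arithmetic mode emulates the s16.15 "accum" format of a digital
neuromorphic core: membrane potential and normalized conductances are kept
on a `2^-15` grid with saturation at ±65,535.99997, and every saturation is
counted in the run record — never silent. Decay constants sit on a `2^-32`
(u0.32) grid, the natural format for factors near 1. Intermediate
arithmetic within one update is carried at full precision with one rounding
on store, which mirrors register arithmetic feeding a 32-bit store.

Two rounding modes coexist deliberately:

* stores of `v` and conductance increments round to nearest, ties to even;
* the conductance **decay multiply truncates toward zero**. Round-to-nearest
  would stall a geometric decay once the per-step decrement falls below half
  a quantum (at `tau_syn_i = 10` ms and `h = 0.05` ms the stall level is
  ~100 quanta), leaving a phantom conductance that visibly shifts
  near-threshold crossings; truncation matches integer-multiply semantics
  and decays to zero.

Bit-for-bit agreement with any particular hardware is explicitly not
promised; the emulation reproduces the format, not the instruction stream.

Synaptic weights are 16-bit codes on a power-of-two grid: the quantum
`q = 2^k` is the smallest power of two with `65,535·q` covering the
projection's peak per-timestep summed input, and the prescribed weight
rounds to the nearest multiple (floor one quantum). Peaks are empirical:
`peak_projection_input()` measures them from a double-precision pilot run
of the same experiment. Under the standard Poisson protocol every weight
encodes within 5% except `pf-PC`, whose combination of the smallest weight
(2×10⁻⁵ μS) and a peak conductance of ~1.7 μS forces a single-bit code
52.6% above the prescribed weight — spanning the periodic-stimulation peak
of ~20 μS would need 19.93 bits.

## Synthetic wiring

The original scaffold places cells with a bounded self-avoiding random walk
and wires them by anisotropic proximity rules; neither algorithm is
reproduced here. Instead:

* `place_cells()` draws positions uniformly inside per-population layer
  slabs stacked along the 900 μm axis (granular, Purkinje — a thin planar
  slab — and molecular layers); the slab thicknesses are a convention, not
  data, and only matter for sphere-based stimulus selection and spatial
  partitioning, both of which have count-based alternatives.
* `build_synapses()` realizes each projection with **exactly** its printed
  synapse count. Uniform mode draws both endpoints uniformly, giving
  near-binomial in-degrees (deviations O(√mean)); spatial mode biases
  source choice by a Gaussian kernel on lateral distance while preserving
  counts, and degenerates to uniform as the kernel widens (tested by a KS
  comparison). Multi-edges are allowed — forbidding them would make the
  dense projections unrealizable at exact counts.

Consequently all mean fan-ins are exact, but the in-degree *variance* is
below the scaffold's (whose convergence rules are over-dispersed), and no
center-surround or other emergent spatial motif is reproduced. Passing
tests therefore validate solver and bookkeeping behaviour on a circuit with
the published first-order statistics, not the scaffold's higher-order
structure; population responses that depend on wiring dispersion (e.g. the
excited-GrC fraction) land near but not on the published single-realization
values. `scale_network()` shrinks populations and synapse counts together
(preserving fan-ins of scaled populations; PC and DCNC sizes are held by
default so that, at reduced scale, their fan-ins shrink proportionally).

## Stimulation protocol

1 Hz Poisson background at every glomerulus for 300 ms; then 50 ms at
`f_peak = 150` Hz (sweepable) for the selected glomeruli; then background
again (650 ms in the full protocol). Selection defaults to the 2,915 Gloms
nearest the population centroid — the count-exact equivalent of the
published 140 μm sphere (41.21% of all Gloms), which is also available but
depends on the unprinted layer geometry. During the burst the background of
selected cells is **replaced**, not superimposed: the difference is 1 Hz in
150 and unresolvable, and replacement keeps the per-step Bernoulli
semantics (at most one spike per source per timestep, matching the
timestep-resolution spike model). Periodic encoding emits synchronized
spikes at `floor(k·1000/(rate·dt))`.

## Analysis

Firing rates are computed in three windows (pre 0–300, stim 300–350, post
350–1000 ms) whose boundaries all shift per population by the input-to-
population latency (GrC/GoC 4 ms, PC 6 ms, SC/BC 9 ms, DCNC 10 ms), clipped
to the run end. A neuron is *excited* if its stimulation-window rate at
least doubles the pre-window rate (a silent-to-active transition counts:
0 → positive trivially doubles; the predicate is isolated in
`classify_response()`), *inhibited* if it falls below half, *neither*
otherwise — an exhaustive, exclusive partition applied uniformly to every
population, relay included. ISI/CV use the full run (population standard
deviation over the intervals; at least three spikes for a CV), cross-run
correlations bin matched neurons' stimulation-window spikes at 5 ms and
omit zero-variance cells, and the PSTH defaults to one bin per timestep.

## Communication model

Neurons map onto abstract cores, 64 per core except one Purkinje cell per
core. A source spike contributes one multicast packet to every *distinct*
core hosting at least one of its targets. The canonical model occupies
exactly 1,583 cores under index partitioning. Spatial partitioning orders
each population by a Morton (z-order) curve over cell positions before
chunking; the published spatial-placement scheme is not fully specified, so
the reported ~41% peak reduction is treated as directional — the tests
assert only that spatial chunking beats random placement on spatially wired
networks and has nothing to exploit on uniform ones. Router-level effects
(drops, reinjection, DMA contention) are out of scope; packet counts are
the proxy.

## Known departures from the reference values

The package encodes the published cell, connection and experiment tables
verbatim, and its double-precision solver was verified against closed-form
LIF periods and an adaptive ODE oracle. Under that configuration:

* The representative single-cell tests for GrC (low 1.4 / high 0.8 Hz
  against 1.2 / 0.8) and DCNC (15.8 / 0.0 against 15.7 / 0.0) reproduce
  their reference outputs, and the DCNC/GoC/GrC behaviour of the full
  network (tonic ~16 Hz DCNC fully silenced during the burst; GoC moving
  from ~18 to ~137 Hz) matches the published network-level numbers.
* The GoC-low, SC and BC single-cell operating points do **not** reproduce
  from the printed parameters: the printed inputs put the GoC test deep
  below threshold (simulated ~0.3 Hz vs. a reported 153.1 Hz) and the
  SC/BC high tests far above it (~460 vs. 47.3 Hz), and no single rescaling
  of excitatory or inhibitory drive reconciles all rows while preserving
  the rows that already match. These operating points appear internally
  inconsistent with the printed tables; the package keeps the tables
  verbatim rather than fitting hidden factors, and its acceptance checks
  report the faithful values.
* In fixed mode, first-spike times agree with the double-precision solver
  within one timestep for all projections except those driving GoC, whose
  steady state sits 0.17 mV above threshold — a tangential approach where
  the crossing time moves ~125 ms per mV, beyond any 2⁻¹⁵-grid arithmetic.
  (The same tangency keeps GoC below 100 spikes in 10 s — 97–98 in both
  modes — which is why the published lead/lag metric excludes it.) The
  100th-spike lead/lag is 0 ms for all Purkinje- and nucleus-target tests;
  the tonic SC/BC tests accumulate ~0.1 ms per period because their
  discrete period straddles a step boundary between the two arithmetics.

## Problem sizes used by the tests

The test suite runs the full-size network once (450 ms, ~326k spikes,
about half a minute), the four headline single-cell experiments at 10 s ×
5 seeds, and everything else on reduced circuits (2–10% scale) chosen so
the whole suite completes in a few minutes; the acceptance script repeats
the full-size run and the single-cell experiments from scratch at the same
sizes.
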