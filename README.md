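# cerebsim

Desk-scale spiking-network simulation of a biophysically constrained
cerebellar microcircuit, with a double-precision reference solver and an
emulated fixed-point back-end of the kind used by digital neuromorphic
hardware.

## The problem

Bottom-up cerebellar models are stress tests for any simulation platform:
granule cells (GrC) make up ~91% of all neurons and feed Purkinje cells (PC)
through fan-ins approaching 28,000 parallel-fibre synapses per cell, so peak
spike traffic converges massively onto very few targets. Running such models
on fixed-point neuromorphic hardware raises two questions this package lets
you study on a desk machine:

1. **Numerics** — can a conductance-based leaky integrate-and-fire network be
   solved accurately with 0.1 ms timesteps and s16.15 ("accum") fixed-point
   state arithmetic, and can 16-bit weights represent both the smallest
   synapse and the largest per-timestep input peak?
2. **Communication** — when neurons are packed onto processing cores, how
   many multicast spike packets must each core absorb per timestep, and how
   much does spatially informed core assignment help?

The circuit is a 400 × 400 × 900 μm block of mouse cerebellum: 96,737
neurons in seven populations (glomeruli `Glom`, granule `GrC`, Golgi `GoC`,
stellate `SC`, basket `BC`, Purkinje `PC`, deep-nucleus `DCNC`) joined by
4,214,215 synapses in 16 projections. The original scaffold's anisotropic
wiring is out of scope; a statistical generator reproduces the exact
per-projection synapse counts (hence all mean fan-ins) with optional
spatial structure.

## The model

Every non-relay neuron follows the conductance-based LIF equations

```
tau_m dv/dt = (v_rest − v) + ĝ_e (E_e − v) + ĝ_i (E_i − v) + î
     dg/dt = −g/tau_syn + Σ g_syn δ(t − t_spike − d)
```

with `ĝ = g·tau_m/Cm` the conductance normalized by the leak conductance
`Cm/tau_m` and reversal potentials `E_e = 0`, `E_i = −90 mV`. The solver uses
*exact integration*: within each 0.1 ms timestep the state is advanced by
`n_sc` sub-cycles (default 2); each sub-cycle decays the conductances by
their exact exponential factor and then applies the closed-form membrane
propagator with conductances frozen over the sub-interval,

```
v_inf  = (v_rest + ĝ_e E_e + ĝ_i E_i + î) / (1 + ĝ_e + ĝ_i)
v     ← v_inf + (v − v_inf)·exp(−h (1 + ĝ_e + ĝ_i)/tau_m)
```

Threshold, reset and refractoriness are resolved once per full timestep.
Spikes travel through a 64-slot delay ring buffer (delays up to 6.4 ms).
The `fixed` back-end quantizes state to the s16.15 grid, decay constants to
a u0.32 grid, and synaptic weights to 16-bit codes on a power-of-two grid
chosen to cover each projection's peak per-timestep summed input; saturation
is counted, never silent.

## Worked example

```r
library(cerebsim)
m <- canonical_model()
mean_fan_in("PC", m)
#> [1] 28665.45

# deep-nucleus cells are tonically active...
exp_single_cell("DCNC", "low", seeds = 1:2)$mean
#> [1] 15.75      # Hz; driven Glom excitation vs. Purkinje inhibition

# ...and fully silenced by the Purkinje burst during stimulation:
ex <- exp_large_scale(scale = 1, duration = 450, seed = 1)  # ~30 s
ex$report[ex$report$population == "DCNC", c("n_inhibited", "stim_mean")]
#>   n_inhibited stim_mean
#>            12         0
```

The first number is the published mean Purkinje fan-in, reproduced exactly
by construction of the synapse counts. The single-cell run drives one DCNC
with 14 excitatory Poisson sources at 0.92 Hz and 30 inhibitory sources at
47.68 Hz for 10 s and reports ~15.8 Hz. The full-scale run executes the
burst protocol (1 Hz background everywhere; 150 Hz for 50 ms to the 2,915
selected glomeruli after a 300 ms pre-period) and classifies all 12
deep-nucleus cells as inhibited, with a 0 Hz firing rate in their shifted
stimulation window.

The 16-bit weight analysis:

```r
bits_required(20, 2e-5)   # peak vs. smallest pf-PC conductance
#> [1] 19.93157
build_codec(0.02e-3, 1.7) # pf-PC weight under the Poisson-condition peak
#> 16-bit weight codec: quantum 2^-15, code 1 (1 bits),
#>   encoded 3.05176e-05 uS (+52.59%), peak 1.7 uS
```

A command-line driver is installed with the package
(`system.file("scripts", "cerebsim", package = "cerebsim")`) with
subcommands `run-network`, `run-single-cell`, `run-single-spike` and
`profile-comms`, each writing rasters, reports and a resolved-config JSON to
an output directory.

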