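---
title: "Dendritic sequence learning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dendritic sequence learning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dendseq` simulates a rate-based two-compartment pyramidal neuron — a
somatic compartment (soma plus basal/proximal dendrites) and a distal
dendritic compartment — and recurrent CA3-like networks of such neurons,
together with the synaptic plasticity rules that let spontaneous firing
sequences act as templates for one-trial spatial learning.  This vignette
describes the model, the choices we made where the circuit description
leaves freedom, and what the bundled synthetic protocols do and do not
establish.

## The neuron model

Each compartment passes its summed input through the same sigmoid
`f(I) = 1 / (1 + exp(-(I - theta_f)))` with threshold `theta_f = 5`.
Somatic activation `x` and dendritic activation `y` interact in two ways:

* **Threshold modulation** — each compartment's drive includes `beta`
  times the partner's activation one millisecond earlier.
* **Gain modulation** — the output rate is `z = (1 + gamma * y) * phi * x`:
  dendritic activation (the calcium-spike mechanism triggered by
  coincident activity) multiplies the somatic output, up to
  `(1 + gamma) * phi`.

Rates are in kHz and time in ms throughout, so the default `phi = 0.08`
is an 80 Hz ceiling and the "1 Hz" inclusion threshold used by the place
field analysis is 0.001 kHz.  Synaptic input is the presynaptic rate
filtered with `tau_L = 10` ms; in the recurrent network every excitatory
pathway additionally carries short-term depression and facilitation
(`D`, `F`; recovery constants 500 and 200 ms, baseline release
probability `U_STF`).

Integration is forward Euler at `dt = 1` ms, which makes the
cross-compartment delay exactly one step.  All time constants are at
least 10 ms, so this resolution is comfortable.  Compartments start at
the zero-input fixed point `f(0)`; traces start at zero; `D = 1` and
`F = U_STF` at rest.  None of these initial conditions are constrained by
the model description; they are the natural resting values.

## The learning rule

Excitatory weights follow a combined rule: a BCM term with a sliding
threshold, plus a coincidence term proportional to `x * y`,

```
dw_som/dt ~ eta * [ (1 - alpha) x (x - theta_som) + alpha x y ] (1 - x) I_som
```

and the dendritic analogue with `y` and `theta_dnd`.  The sliding
thresholds are `theta = c0 * E^2` where `E` low-pass filters the
activation with `tau_mean = 60` s.  At `beta = 0` the rule ascends the
objective

```
L = (1 - alpha) (E[x^2]/2 + E[y^2]/2 - c0 E[x]^3 - c0 E[y]^3) + alpha E[x y]
```

so `alpha` interpolates between PCA-like Hebbian learning within each
compartment and CCA-like learning of the correlated component across
compartments.  `objective_value_frozen()` writes the homeostatic terms as
`theta * E[x]` with the threshold treated as an external constant; this
functional takes the same value at the operating point and its
finite-difference gradient matches the update term exactly, which is how
the test suite verifies the gradient property (treating the sliding
threshold as slowly varying relative to the weights).

Weight changes are delayed through a second-order variable with
`tau_w = 1` s, decay at `eta_decay = 1e-7`/ms, and fluctuate with
per-step Gaussian noise of standard deviation `sigma_w * sqrt(dt)` (the
continuous-time noise term is not given a discretization in the model
description; this scaling makes the strength dt-invariant with `sigma_w`
calibrated at 1 ms).  Weights are clipped at zero after every step and
recurrent self-connections are pinned to zero.  The noise applies to
excitatory weights only; the dendritic inhibitory weights evolve without
a noise term, following their governing equation literally.

Dendritic inhibitory weights use the same functional form with a fixed
threshold `theta_inh = 0.5` and learning rate `eta_inh`.  An alternative
"calcium-BCM" rule is provided (`rule = "calcium_bcm"`), in which
effective activities `z_som = (1 - alpha_som) x + alpha_som x y` (and the
dendritic analogue) enter a plain BCM bracket and also drive the sliding
thresholds.

## Inhibitory feedback

A population of `n_inh` inhibitory readouts pools the filtered pyramidal
outputs through fixed random weights, column-normalized so that each
pyramidal cell contributes `1/n_inh` in total.  Somatic inhibition is the
fixed weight `v_som` times the summed readouts; dendritic inhibition is
the plastic matrix `v_dnd` times the readout vector.

Two scale choices here are genuinely open and matter a great deal:

* **`v_som` for networks.**  The value 20 is specified only for the
  two-cell circuit with a single readout.  Because the pooled readout sum
  grows with network size, a fixed `v_som` makes the excitation–
  inhibition balance depend on the neuron count.  `scale_v_som()` keeps
  the balance size-invariant; the network presets use a reference weight
  of 26.7 (at 300 cells and 100 readouts), calibrated once at desk scale
  so that triggered sequences propagate during immobility, theta drive
  does not saturate the population during running, and single-trial
  learning functions.
* **The dendritic readout scale (`dnd_gain`).**  Only the *shape* of the
  readout weights is constrained (column-normalized); their absolute
  scale is not.  This scale sets how fast plastic dendritic inhibition
  accumulates on a dominating ensemble.  With the same normalization as
  the somatic pool, suppression takes minutes, far slower than the
  within-visit ensemble turnover the model is supposed to produce (a
  newly dominant ensemble must be retired within a traversal so that
  other ensembles can represent later episodes).  The presets use
  `dnd_gain = 40`, which puts ensemble turnover at the one-to-few-seconds
  scale.  Facilitating dendrite-targeting interneurons would achieve the
  same effect biologically; here the gain is a single static constant.

An optional switch (`stp_pyr_pool`) applies the recurrent short-term
plasticity factor to the pyramidal-to-interneuron traces (so that the
interneurons read exactly the recurrent traces).  It is off by default:
with the run-phase release probability of 0.03 this reading removes
nearly all feedback inhibition during running and the network saturates.

## Input and behavior generators

All inputs are synthetic.  Slow sources are Ornstein–Uhlenbeck processes
(`tau_s = 10` ms, `sigma_s = 0.1`), advanced with the exact-in-
distribution update, so the stationary variance is `sigma^2 tau / 2`
for any `dt`.  The single-cell protocols build input-neuron currents from
shared or disjoint sources (minority groups A/A' of 10 neurons, majority
groups B/B' of 40), with per-neuron white noise (`sigma_n = 0.1`), and
convert them to rates through `phi_input * f(current)`.

The behavioral protocols are: a 1D track (rest to 10 s, three runs to
50 s; the first ramp is implemented as `(t-10)/5`, the unique continuous
reading of the printed schedule), a Y-maze (10-s arm visits, three arms
in rotation), and a branching track.  EC inputs are place-tuned
(Gaussian, `A_F = 5`, `sigma_F = 0.1`), grid-tuned
(`A_grid exp(c_grid cos(2 pi pos / period - phase))` with random phase
and period per cell), or position-independent distractors driven by slow
private sources.  During running every EC current carries half the theta
drive minus a 0.5 baseline plus OU noise (`sigma_n = 1`; the smaller 0.1
applies to the external somatic noise — the two values are stated in
different contexts and we keep both); during immobility EC neurons
receive noise only.  Theta is a 7-Hz sine of amplitude 10 gated by
locomotion.  Triggers (the dentate-gyrus stand-in) are Poisson at 1 Hz
during immobility (10-ms pulses) plus a forced pulse at the first run
onset; on the 1D track the trigger adds +amplitude to the first ten
neurons and -amplitude to the rest.

During movement the recurrent release probability switches from 0.5 to
0.03 (EC synapses keep 0.5) and the recurrent facilitation variables are
set to 0.03 instantly at run onset; depression variables are left
untouched (nothing is said about them, and they relax on their own).

## Simulation engines

Every operation exists as a small documented R function, and the two
simulators (`simulate_cells()` for the single-cell protocols,
`run_network()` for the recurrent network) have a pure-R reference path
and a compiled core.  The compiled cores mirror the R steppers operation
for operation; the test suite runs both on identical deterministic
problems and requires agreement at floating-point accuracy.  The cores
draw their randomness from a self-contained xoshiro256++ stream with a
ziggurat normal sampler, so a run is reproducible from a single integer
seed regardless of the R session state; the R-level setup (initial
weights, receptive-field centers, trigger schedules) uses the R RNG, so
`set.seed()` plus the engine seed fixes a simulation bit-for-bit.

## Study conditions and what the tests show

Durations for the single-cell experiments are not specified by the model
description; we chose them from convergence of the weight trajectories
(contrasts plateau by roughly 500–600 s at `eta = 0.2`): 1500 s for the
one-cell protocols, 900 s for the two-cell separation experiment.  The
three-phase stability protocol is fully specified (300/300/600 s) and
used as printed.

The recurrent-network protocols are run at desk scale in the tests
(100 CA3 / 150 EC for the track, three groups of 50 for the Y-maze,
40 + 2x60 and the full 100 + 2x150 for the branching network), with the
full sizes remaining the preset defaults.  The weight-collapse boundary
of the single-cell phase diagram sits at higher `beta` here (complete
collapse at `beta >= 8`, not at 4): the collapse requires the
compartments' baseline activations to be large enough that the
threshold-modulation loop can ignite, and that depends on the overall
input-current scale, which is not pinned down by the stated parameters.

Passing tests show that the implemented equations produce the documented
phenomena under the synthetic protocols: they do not show anything about
real hippocampal tissue, about robustness across the full parameter
space, or about spiking implementations.  Known limitations: place-field
quality in the scaled network is sensitive to the two inhibitory scale
choices discussed above; the single-compartment control with
`eta = 0.5` can reach within a factor of two of the two-compartment
model on the track protocol at desk scale; and the branching-replay
statistics are noisy at small branch sizes, where the initial weight
fluctuations alone bias the branch choice.
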