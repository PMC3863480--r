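---
title: "Self-structuring delay-line columns as a neural Hough transform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-structuring delay-line columns as a neural Hough transform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(columnhough)
```

## The model

`columnhough` simulates a feedforward spiking network that maps
spatiotemporal binary patterns — bars of different slopes, or discretized
sinusoids — onto an ordered column of orientation-selective feature
neurons. The computation it learns is a Hough transform in space-time: an
extended stimulus (a whole bar) is collapsed onto a single point of an
ordered feature axis, the way simple cells in visual cortex respond
selectively to oriented edges.

The architecture is a regular lattice. `m` input neurons each feed one
*cortical column*: a chain of `n` *block segments*. Inside every segment
the signal path bifurcates into a **direct path**, crossed in one clock
step, and a **delay path** through a delay neuron, which adds exactly one
extra clock step; the two branches recombine at a junction. Which branch a
signal takes is governed by the antagonistic weight pair
`(w_direct, w_delay)` with `w_direct + w_delay = 1`. After the junction of
segment layer `k`, every column synapses (hardwired, weight 1) onto output
neuron `k`, whose threshold is the number of signal paths minus one
(`m - 1`): it spikes only when **all** `m` column signals arrive at its
layer in the same clock step — a planar wave front. Off that layer the
per-column velocity differences tear the front apart, so a trained network
emits a *time-and-place code*: the identity of the firing output neuron
signals the pattern class, its latency the relative timing.

Patterns are presented row-serially: each image row is applied to the
input layer at one integer clock step. The input layer itself is clamped
direct (`w_direct = 1`), wiring the zero-skew class (the horizontal bar,
all channels simultaneously) straight to output 0.

### Path selection and learning

During training, each bifurcation draws a uniform random number and takes
the direct path with the Boltzmann probability

$$P_\text{direct} = \frac{e^{w_\text{direct}/T}}{e^{w_\text{direct}/T} +
e^{w_\text{delay}/T}}, \qquad P_\text{delay} = 1 - P_\text{direct},$$

at its layer's temperature `T`. If at least one output spikes, the
lowest-index spiking output `k` triggers learning on its own layer: every
layer-`k` segment reinforces the path its signal actually took,

$$w_\text{sel} \leftarrow w_\text{sel} + (1 - w_\text{sel})\,\alpha,
\qquad w_\text{desel} \leftarrow w_\text{desel} - w_\text{desel}\,\alpha,$$

and layer `k`'s temperature drops by `delta_T` (never below `T_min`). The
two increments cancel, so the pair stays complementary and inside
`[0, 1]`, with `(1, 0)` as fixed points: weights binarize into gating
switches. Because an output can only spike when its layer's sampled
configuration compensates the stimulus onset skew exactly, reinforcement
is self-consistent — the spike is the teaching signal, and learning is
fully unsupervised. Layers settle sequentially: layer 1 conditions the
arrival times layer 2 sees, and so on down the chain.

The update rule above is the package's reading of the learning rule: the
printed recurrence it is based on is not well formed (its new value
appears on both sides), and this reading is the one that preserves
complementarity and drives the larger weight to 1 — the stated end state.
The per-spike increment ±ε is state-dependent and controlled solely by
`alpha`; there is no separate ε parameter.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `T_max` | 1.0 | – | initial per-layer temperature; near-random gating |
| `T_min` | 0.05 | – | floor; gating effectively deterministic for binarized weights |
| `delta_T` | 0.005 | – | decrement per learning spike; floor reached after 190 spikes |
| `alpha` | 0.01 | – | learning slope; ~618 spikes binarize a weight to within `1e-3` |
| `convergence_tol` | 1e-3 | – | distance from {0, 1} at which a weight counts as settled |
| `max_presentations` | 1e5 | presentations | cap; exceeding it is a reported outcome, not an error |
| clock step | 1 | ms (via `clock_ms` in the protocol exporter) | delay surcharge = 1 step |

The source model states no numeric values for the annealing schedule or
learning rate and describes production runs with a very low `alpha` and
several hundred thousand presentations. The defaults here are desk-scale
study conditions chosen once: the anneal is smooth (≥190 spikes per layer
to reach the floor) and a 2×2 network converges in roughly 1.5–2 thousand
presentations, a 3×3 in a few thousand. They are deliberately not tuned
per experiment.

## Worked example: the minimal microcircuit

The smallest interesting network has two input neurons, four delay
neurons, and two output neurons, trained on two stimuli played like a
piano on two electrodes: `V` (both channels at `t0`) and `D` (channel 2 at
`t0`, channel 1 at `t1`). Its target truth table: `V` fires output 0, `D`
fires output 1.

```{r minimal, eval = FALSE}
pats <- two_electrode_set()
cfg <- network_config(seed = 42)
res <- train(build_network(2, 2, cfg), pats)
res$converged
truth_table(res$network)
convergence_report(res)$truth_table_stable_at
```

The only feasible configuration delays the leading column (channel 2) at
layer 1, so both signals meet at output 1's junction for `D` while `V`
coincides at the clamped input layer. `brute_force_configs()` confirms by
exhausting all `2^(m(n-1))` admissible configurations that this
configuration is unique, and every converged training run lands on it.

## The analytic reference configuration

`analytic_config()` derives the converged weight setting directly: for
pattern `k`, column `i`'s cumulative delay count over layers `1..k` must
equal the pattern's onset skew at that column, so all signals coincide at
layer `k`. The per-layer delay bit is the increment of this requirement
between consecutive classes; the half-up staircase rasterization of bars
guarantees each increment is 0 or 1, i.e. realisable within one layer.
Among the feasible placements this puts each delay in the earliest
possible layer; the construction is always cross-checked by propagation
before it is returned, and — wherever enumeration is tractable — it is a
member of the brute-force feasible set.

## The synthetic stimuli

Bars are rasterized as `step(i) = round(i·k/(m-1))` with half-up rounding;
this reproduces the two endpoints fixed by the model (horizontal: all
channels at one step; 45°: one channel per step) and yields monotone onset
skew in between. Sinusoids take one active channel per step from a
rounded, clipped sine trace; the discretization convention (rounding,
clipping to the channel range) is the package's own, as no formula is
given in the source model. The perturbation module adds uniform integer
timing jitter and Bernoulli event dropout — a deliberately minimal noise
model, chosen because the robustness claims under study concern timing and
structural loss, not biophysical noise.

What these stimuli do *not* emulate: real MEA recordings (spike sorting,
stimulation artifacts), electrode geometry, pulse shapes and amplitudes,
astrocyte-mediated plasticity, or subthreshold membrane dynamics. Passing
tests therefore demonstrate the computational claims of the circuit model
— not that a cultured network will reproduce them.

## Numerical choices and degenerate inputs

- `P_direct` is computed as `plogis((w_direct - w_delay)/T)`, algebraically
  identical to the two-state Boltzmann ratio and stable at small `T`.
- Delay path transit is 2 steps vs 1 direct. Only the +1 surcharge is
  fixed by the model; a uniform base offset shifts all spike times equally
  and cannot change coincidence structure.
- Ties: if several outputs reach coincidence in one presentation, all are
  recorded (one spike max per output), but only the lowest-index spiking
  output learns — consistent with sequential settling. `decode()` reports
  multi-output traces as `ambiguous` and silent traces as `none`; neither
  is ever coerced to a class.
- Temperatures anneal on any learning-triggering spike, including spikes
  of the clamped input layer (harmless: its weights never move).
- Empty patterns propagate to an empty trace, not an error. Ablating every
  column, out-of-range classes, non-positive frequencies and malformed
  network documents are rejected with explicit messages.
- Training on an already-binarized network returns immediately with zero
  presentations used; `alpha = 0` runs to the cap and reports
  non-convergence.
- Weight trajectories are recorded per presentation only for small nets
  (`m·(n-1) ≤ 8` by default) to bound memory; the 2×2 truth-table
  stability scan relies on this record.
- All randomness flows through R's session RNG; a network object carries
  its RNG state and presentation counter, so a run saved mid-training and
  resumed from disk reproduces the uninterrupted trajectory bit for bit
  (weights serialize at 17 significant digits).

## Design choices where the design was open

- **Update scope.** On a spike of output `k`, only layer-`k` segments
  learn. Earlier layers are treated as already conditioned, later layers
  untouched; this matches per-layer temperatures and the sequential
  settling account, though the scope is not stated explicitly in the
  source model.
- **Learning on any spike.** Whether learning should be restricted to
  "correct" spikes is unspecified; the rule here is applied on any
  (lowest-index) spike, keeping it strictly unsupervised. The oracle
  membership tests measure the consequence: converged configurations are
  nevertheless always feasible.
- **Presentation order.** Cyclic round-robin by default, with an optional
  seeded shuffle; the alternation itself is not load-bearing, since each
  class can only trigger learning at its own layer.
- **Test distribution.** "Random test set" is interpreted as the training
  classes in random order, optionally jittered; no separate held-out
  distribution is defined by the model.

## Problem sizes used in the shipped checks

The test suite trains 2×2 networks across 20 seeds (each converging in
under ~2,000 presentations), 3×3 networks across 20 seeds for the
sequential-settling property, enumerates feasible sets up to
`2^12` configurations, and verifies the analytic construction for square
sizes 2–9. These sizes were chosen as the smallest that exercise every
mechanism — clamped layer, multi-layer settling, oracle cross-checks —
while keeping any single check in the seconds range.

## Known limitations

- The analytic construction requires bar-like sets (one event per column
  per pattern, zero skew in class 0); sinusoid sets are verified by
  brute force only, within the enumeration bound.
- Only the binary direct/delay choice is learnable; conduction delays,
  inhibition and arbitrary topologies are out of scope.
- With the full threshold `m - 1`, the loss of a single column silences
  the network entirely; robustness requires lowering thresholds
  (`threshold_offset`), which is exactly the trade-off the perturbation
  module is there to quantify.
- Convergence of the presentation loop is stochastic; it is overwhelmingly
  reliable at the shipped study conditions but not guaranteed for
  arbitrary parameter combinations, which is why non-convergence is a
  first-class reported outcome.
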