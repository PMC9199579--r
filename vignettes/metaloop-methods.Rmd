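---
title: "Two-loop meta-optimization: models, testbeds, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-loop meta-optimization: models, testbeds, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaloop)
```

## The two-loop model

`metaloop` separates *what is simulated* from *how its parameters are
searched*. The inner loop is an **optimizee**: any simulation that maps a
named parameter set (an *individual*) to a fitness vector. The outer loop
is an **optimizer**: a population-based algorithm that turns one evaluated
generation — individuals plus fitness records — into the next population.
`run_experiment()` orchestrates the cycle (evaluate, record, breed, clip to
bounds), appends every generation to a persistent *trajectory*, and keeps
multi-objective fitness vectors scalarized by a dot product with the
configured weight tuple. Maximization is the universal convention;
minimization problems return the negated loss.

Reproducibility is a contract, not a hope: every evaluation receives a seed
hashed from (experiment seed, generation, individual id)
(`derive_seed()`), and the optimizer's own RNG stream is re-seeded per
generation from the same source. Serial and forked-parallel evaluation of a
generation are therefore bit-identical, which the suite asserts. A failed
evaluation keeps its slot with fitness `-Inf` so population-based
optimizers see a constant population size; a generation where *every*
evaluation fails aborts, since no optimizer step is meaningful then.

The trajectory store is JSON — self-describing, text-only, with a
per-generation CSV export for external analysis. Non-finite fitness values
are encoded as strings, since JSON has no `-Inf` literal.

## The optimizers

All seven optimizers share the `opt_init()`/`opt_step()` interface and are
registered by name for the YAML/CLI front end.

* **Ensemble Kalman inversion** (`enkf_update()`): each member moves by
  `u + C_ud (C_dd + gamma I)^{-1} (y - g(u))`, with population-normalized
  (1/n) ensemble covariances and a Cholesky solve that `gamma > 0`
  guarantees. Parameters are normalized to [0, 1] using *fixed declared
  bounds*, not per-generation min-max, so the mapping is stable across
  generations. The rank-based modification (`rank_replace_perturb()`)
  replaces the worst `floor(f n)` members with rank-paired copies of the
  best `floor(f n)` plus Gaussian noise; the pairing is rank-to-rank and
  the noise scale is a free parameter (we default to 0.5 weight units in
  the reservoir testbed) — both free choices of this design.
* **Genetic algorithm**: tournament selection (size 3), blend crossover
  (alpha 0.5), Gaussian mutation whose sigma is expressed as a *fraction of
  each parameter's range* so mixed-scale specs mutate sensibly, plus a
  Hall of Fame whose best entry is non-decreasing by construction. The
  operator choices mirror common evolutionary-computation library
  defaults; they are declared, configurable, and tested rather than
  implicit.
* **Evolution strategies**: search-gradient ascent with rank-standardized
  fitness; mirrored perturbations recover the gradient direction exactly on
  a linear surface (tested algebraically).
* **Gradient ascent**: black-box gradients estimated by least-squares
  regression of probe fitnesses on probe offsets (pseudoinverse for
  rank-deficient probe sets). The probe-regression estimator is our choice;
  estimating gradients this way is a design choice of this package.
* **Multi-gradient ascent**: several individuals each carry a *cloud* of
  parameter combinations evaluated in one expanded batch; the best
  combination becomes the new center, nudged along the improvement
  direction by the learning rate, and a fresh grid cloud is generated with
  the half-range shrunk by 0.9 per generation. The shrink-and-recenter
  rule is this package's concrete definition of how the new parameter
  range follows the best fitness.
* **Simulated annealing**: per-chain Metropolis acceptance
  `exp(delta/T)` with exponential (`T0 c^t`), linear, and logarithmic
  cooling.
* **Cross-entropy**: Gaussian refit to the elite fraction with smoothing
  toward the previous distribution and a diagonal covariance floor.
* **Grid search**: the Cartesian product with both endpoints, capped, with
  the error reporting the offending `resolution^dimension` count.

Natural evolution strategies and parallel tempering are named in the
surveyed optimizer families but not described there; they are out of scope
and deliberately not implemented.

## The LIF simulator

The spiking testbeds need a network simulator, not a specific engine, so
`simulate_network()` implements the smallest adequate one: current-based
LIF point neurons (tau_m 10 ms, rest/reset -70 mV, threshold -55 mV,
refractory 2 ms), forward-Euler at dt 0.1 ms, delta synapses with
integer-step delay ring buffers, piecewise-constant external drive, and
optional Poisson background impulses. Neurons flagged as *sources* are
rate-coded Poisson generators (their drive is a rate in Hz) — that is how
pixel intensities enter the reservoir. Membrane state, refractory counters
and in-flight delayed currents can be carried across calls, which is what
closed-loop control requires.

Two numerical points matter. First, accuracy: the suite checks the
simulated f–I curve against the closed-form LIF rate
`1000 / (t_ref + tau_m log((V_inf - V_reset)/(V_inf - V_thr)))` to within
2% at dt = 0.1 ms. Second, cost: Bernoulli-per-step background and source
spiking is realized by geometric gap sampling, touching the RNG once per
impulse rather than once per neuron-step; statistically identical,
an order of magnitude faster.

The mountain-car episode additionally has a compiled closed-loop fast path
(`engine = "cpp"`), because 110 environment steps times 200 integration
steps times tens of thousands of episodes would otherwise be dominated by
interpreter round trips. It is asserted *bit-identical* to the R
composition of `bin_index()`, `simulate_network()` and
`winner_take_all()` — including floating-point association in the physics
update — so the fast path is an optimization, never a second model.

## Testbeds and what they do (and do not) show

**Reservoir digit classification.** `build_reservoir()` realizes the
reference architecture: 768 pixel-driven inputs, 1600 + 400 reservoir
neurons with 6%/8% outdegree caps, three 12-neuron output clusters
(10 excitatory, 2 inhibitory), recurrent within a cluster and never
across, each output neuron pooling exactly 800 reservoir sources — 28 800
readout synapses at full scale, shrinking proportionally with `scale`.
Weights are drawn from the reference normals, N(70, 50) excitatory and
N(-90, 50) inhibitory; because our synapses are delta-current (a weight is
a millivolt kick, not a conductance), the builder converts units with
efficacy factors (0.1 for input/recurrent, 0.01 for the readout). Without
that conversion a 70 mV kick fires every neuron at the refractory ceiling
and class information vanishes. A per-neuron indegree figure of 640/460 sometimes quoted for this
architecture cannot be reconciled with 800 x 12 x 3 = 28 800; we
implement the latter.

`train_reservoir()` runs the modified-EnKF pipeline on synthetic
three-class digits (`synthetic_digits()`: geometric glyphs at intensity
255, 2-pixel jitter, salt noise; nearest-centroid separable by
construction). Choices worth knowing: the softmax is applied to cluster
rates divided by a 5 Hz temperature; all members of a generation share one
simulation seed (common random numbers), so ensemble prediction
differences reflect weights, not Poisson noise; the EnKF target is the
image-major concatenation of one-hot labels, matching the concatenated
softmax rows; gamma defaults to 0.5, the reference setting for this use case. At desk scale
(scale 0.1, ensemble 20, 30 generations) the best member exceeds fitness
0.8; improvement beyond that point comes mostly from the rank-replacement
exploration, not from ensemble consensus — the surrogate for the full-scale
classification setting is deliberately modest, and passing it says nothing about
handwritten-digit images, batch sizes of thousands, or 98 x 28 800
ensembles.

**Single-cell trace fitting.** The adaptive integrate-and-fire
`toy_cell_trace()` stands in for a morphologically detailed neuron: leak,
spike-triggered adaptation, spikes pasted at a fixed height so
threshold-based spike features have support. The recovery experiment
(`fit_cell()`, GA with population 100 over 200 generations, the reference
configuration) plants two parameters (leak conductance and reversal) and
recovers them within 5% across seeds — but only with *subthreshold*
stimulus clamps. We measured the suprathreshold square-loss surface in
(g_l, e_l) to be a one-grid-point needle: any spike-time misalignment
dominates Eq.-style square loss, and no population optimizer finds the
peak. That ruggedness is precisely the motivation for the feature-based
fitness (mean-difference L and threshold-selected S), which is implemented
(`fitness_mode = "features"`, Eq.-3-style interleaved vectors) and tested,
while the smooth subthreshold setting is what makes the *recovery*
acceptance meaningful. The square loss keeps the 1/T^2 prefactor of its defining form,
with `normalization = "mean"` as an escape hatch; S is defined as 0 when
no reference sample crosses the threshold.

**Foraging colony fitness.** Only the event-log accounting is in scope:
`colony_fitness()` scores timestamped (move, rotate, drop-pheromone, rest,
food-touch, nest-return) events with the reference constants (-0.02, -0.05,
-0.25, -0.5, +1.5, +220), is additive over concatenated logs, and reads
external logs from CSV. The 12-10-4 ant brain builder (250 synapses in the
documented stable order; delays initialized on {1..6} and clipped to
[1, 5] afterward, preserving that asymmetry of the reference design) makes the
weight-vector contract concrete; the agent-based world itself is not
simulated.

**Whole-brain FC–SC fitting.** The regional model is an abstract noisy
Stuart–Landau oscillator with index-distance conduction delays — only the
fitness pipeline fidelity is claimed, not any particular neural-mass
model. `fc_sc_fitness()` computes FC as pairwise Pearson correlation,
normalizes SC by its maximum, and correlates the upper-triangular
off-diagonal entries (the FC diagonal is identically 1 and would only
inflate the score). `fit_fc()` runs multi-gradient ascent (4 individuals,
cloud 64, learning rate 0.01) on a deterministic objective (fixed noise
seed per run), which is what makes a dense-grid oracle comparison exact
rather than a race between noise realizations; the optimum found is within
5% of (in practice above) the 12 x 12 grid's best.

**Mountain car.** Physics uses the standard constants (force 0.001,
gravity 0.0025 cos(3p), velocity bound ±0.07, goal 0.5, valley starts).
Position and velocity are discretized into 30 bins each; the two active
inputs are driven by a DC amplitude calibrated through the closed-form f–I
curve to sit near the 500 Hz refractory ceiling. Two decisions came out of
measurement rather than preference. First, the *encoder range for
velocity* defaults to the wide figure [-0.7, 0.7] of the reference design, under which
every reachable velocity falls into one of the two central bins — an
effective sign-of-velocity code. With the full-resolution ±0.07 encoder
the GA still reaches the goal, but its champions fail the 100-episode
success criterion (measured means 120–180 steps); with the sign code they
generalize (around 105–115 steps). Second, evolution runs its full 400
generations by default: stopping at the first fitness-0.5 individual
selects a lucky episode, not a robust policy; continued selection pressure
is what hardens the population. Training episodes cap at 110 steps and
evaluation episodes at 200, per the reference protocol.

Because training fitness is the maximum position of a *single* random
episode, the highest-fitness individual of a run is partly a draw of
episode luck — we measured champion-to-champion spreads of ±8 steps in
evaluated mean steps-to-goal under identical settings, with no selection
rule (best-ever, final generation, common-random-number starts) reliably
better than another. The package therefore nominates its champion by
standard model selection (`mc_select_champion()`): shortlist the few
highest-fitness individuals of each run, validate each on a handful of
held-out episodes, and nominate the best validated candidate. Reported
evaluations always use fresh episodes seeded independently of
validation.

## Problem sizes and defaults

The suite and the acceptance script run the testbeds at desk scale, chosen
once as what a workstation-level replication of each pipeline looks like:
reservoir scale 0.1 with a 20-member ensemble and 30 generations;
mountain-car GA with population 32 up to 400 generations and 3 seeds;
toy-cell GA at the reference population 100 / 200 generations over two
clamps of 100 ms at dt 0.25 ms; FC–SC fitting on a 10-region modular
matrix with 4 x 64 evaluations per generation for 30 generations. The
full reference configurations (scale 1, 98-member ensembles) remain
reachable through the same arguments.

## Known limitations

* The LIF model is current-based with delta synapses; no conductances, no
  plasticity, no multi-compartment cables. Efficacy conversion factors are
  a modeling device, not biophysics.
* The EnKF testbed demonstrates the update's mechanics and the
  rank-replacement's exploratory value at desk scale; its learning curve
  is not a quantitative surrogate for full-scale behavior.
* The oscillator surrogate's FC structure is generic; no claim is made
  about matching any specific neural-mass model's dynamics.
* Checkpoint/resume, HPC schedulers, and live visualization are out of
  scope; the runner interface ships with a local fork-based pool only, and
  the CSV exchange (`run_external()`) is the sole coupling for non-R
  optimizees.
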