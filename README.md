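# metaloop

Two-loop meta-optimization for simulation-based models in computational
neuroscience. Many models of interest — spiking networks, single-cell
models, whole-brain mass models, embodied agents — expose dozens to
thousands of parameters, and only narrow regions of that space produce the
dynamics a study needs. `metaloop` separates the problem into an **inner
loop** (the *optimizee*: one simulation mapping a named parameter set, an
*individual*, to a fitness vector **f**) and an **outer loop** (the
*optimizer*: a population-based algorithm mapping a generation's
parameters and fitnesses to the next generation). Generations are
embarrassingly parallel, every run is reproducible from `(config, seed)`
— bit-identical whether evaluated serially or on a forked worker pool —
and the full history is persisted as a *trajectory*.

## What is in the box

**Core framework** — parameter specs with bounds and integer kinds
(`param_spec()`, `create_individual()`, `apply_bounds()`), fitness
scalarization by a weight tuple (`weighted_fitness()`), parallel
generation evaluation with per-individual derived seeds and fault
isolation (`evaluate_generation()`), orchestration (`run_experiment()`),
trajectory persistence as self-describing JSON plus CSV export, a YAML run
configuration, a CSV-exchange adapter for optimizees written in any
language (`run_external()`), and a thin CLI (`inst/cli/metaloop.R`).

**Seven optimizers** — ensemble Kalman inversion with the
rank-replace-perturb modification

```
u_j <- u_j + C_ud (C_dd + gamma I)^-1 (y - g(u_j))
```

(population-normalized ensemble covariances, parameters normalized to
[0, 1] over fixed declared bounds), a genetic algorithm with tournament
selection, blend crossover, Gaussian mutation and a Hall of Fame,
evolution strategies with rank-standardized search gradients, gradient
ascent by probe regression, multi-gradient ascent over per-individual
parameter clouds (expand/compress), simulated annealing with exponential,
linear and logarithmic cooling, cross-entropy, and exhaustive grid search.

**A LIF network simulator and testbeds** — a compiled forward-Euler
leaky integrate-and-fire simulator (delta synapses, integer delay queues,
Poisson sources and background, state carried across calls, f–I-verified
against the closed form), with four end-to-end pipelines:

* a spiking reservoir (liquid state machine) classifying synthetic digit
  images, readout trained by the modified ensemble Kalman inversion
  (`build_reservoir()`, `synthetic_digits()`, `train_reservoir()`);
* a 60–5–3 spiking policy network evolved to solve the mountain-car
  control task (`build_mc_policy()`, `run_mc_episode()`,
  `evolve_mc_policy()`, `mc_evaluate()`);
* an adaptive integrate-and-fire toy cell for electrophysiology trace
  fitting with square-loss and spike-feature fitness
  (`toy_cell_trace()`, `fit_cell()`);
* a coupled-oscillator surrogate for matching simulated functional
  connectivity to structural connectivity by multi-gradient ascent
  (`oscillator_network()`, `fc_sc_fitness()`, `fit_fc()`);

plus the 12–10–4 foraging-agent brain builder and the event-log colony
fitness with its reference per-event constants (`build_ant_brain()`,
`colony_fitness()`).

## A worked example

Genetic-algorithm search on the 2-d Rastrigin surface (global optimum 0 at
the origin, maximization convention):

```r
library(metaloop)
cfg <- experiment_config(
  optimizee = "rastrigin", optimizer = "ga",
  optimizee_params = list(dim = 2, low = -5.12, high = 5.12),
  optimizer_params = list(mutation_sigma = 0.05),
  n_pop = 60, n_generations = 40, seed = 42)
traj <- run_experiment(cfg)
print(traj)
#> <trajectory> 40 generation(s), seed 42
#>   population 60, best scalar fitness -1.84272e-06 (generation 32)
best <- trajectory_best(traj)
best$individual$values$x
#> [1] 2.99e-05 9.11e-05
```

The trajectory holds every generation's individuals and fitness records;
`trajectory_fitness_history(traj)` gives the per-generation best (here
rising from -13.8 to essentially 0), `persist_trajectory()` /
`load_trajectory()` round-trip it to JSON, and `export_trajectory_csv()`
flattens it for external tools. The same run works from the shell:

```sh
Rscript inst/cli/metaloop.R run --config config.yaml --seed 42 --outdir results/
Rscript inst/cli/metaloop.R list
```

A testbed example — evolve the spiking mountain-car policy, nominate a
champion by held-out validation, and evaluate it on fresh episodes:

```r
traj <- evolve_mc_policy(n_pop = 32, n_generations = 400, seed = 1)
champ <- mc_select_champion(traj, k = 5, n_val = 10, seed = 2)
ev <- mc_evaluate(champ$weights, n_episodes = 100, max_steps = 200, seed = 3)
ev$mean_steps; ev$success_rate
#> [1] 105.3
#> [1] 1
```

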