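# Minimal run configuration: GA on the 3-d sphere surface.
#   Rscript inst/cli/metaloop.R run --config inst/examples/sphere-ga.yaml
experiment:
  name: sphere-ga-demo
  seed: 1
  n_generations: 40
  population: 50
  weights: [1.0]
  workers: 1
optimizee:
  name: sphere
  params:
    dim: 3
    low: -5
    high: 5
optimizer:
  name: ga
  params:
    tournament_size: 3
    crossover_prob: 0.7
    mutation_prob: 0.3
    mutation_sigma: 0.05
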