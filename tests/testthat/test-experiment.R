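test_that("grid search recovers the exhaustive argmax", {
  optee <- list(spec = param_spec(x = list(low = 0, high = 1)),
                simulate = function(ind, seed) -(ind$values$x - 0.3)^2)
  cfg <- experiment_config(optee, optimizer_grid(101L), n_pop = 1L,
                           n_generations = 1L, seed = 1L)
  traj <- run_experiment(cfg)
  expect_equal(trajectory_best(traj)$individual$values$x, 0.3)
  expect_length(traj$generations[[1]]$individuals, 101)
})

test_that("GA runs keep the best-so-far fitness non-decreasing", {
  cfg <- experiment_config(sphere_optimizee(2), optimizer_ga(),
                           n_pop = 20L, n_generations = 50L, seed = 4L)
  traj <- run_experiment(cfg)
  h <- trajectory_fitness_history(traj)
  expect_true(all(diff(cummax(h)) >= 0))
  expect_gt(max(h), h[1])
})

test_that("a run is fully reproducible from (config, seed)", {
  cfg <- experiment_config("sphere", "ga", optimizee_params = list(dim = 3),
                           n_pop = 12L, n_generations = 6L, seed = 11L)
  t1 <- run_experiment(cfg)
  t2 <- run_experiment(cfg)
  expect_identical(t1, t2)
  path1 <- withr::local_tempfile(fileext = ".json")
  path2 <- withr::local_tempfile(fileext = ".json")
  persist_trajectory(t1, path1); persist_trajectory(t2, path2)
  expect_identical(readLines(path1), readLines(path2))
})

test_that("bounds hold for every individual of every generation", {
  for (opt in list(optimizer_ga(), optimizer_es(n_offspring = 10),
                   optimizer_sa(), optimizer_ce())) {
    cfg <- experiment_config(sphere_optimizee(2, low = -1, high = 1), opt,
                             n_pop = 10L, n_generations = 8L, seed = 2L)
    traj <- run_experiment(cfg)
    for (gen in traj$generations) {
      for (ind in gen$individuals) {
        expect_true(all(ind$values$x >= -1 & ind$values$x <= 1))
      }
    }
  }
})

test_that("population size is conserved across optimizer steps", {
  for (opt in list(optimizer_ga(), optimizer_sa(), optimizer_ce())) {
    cfg <- experiment_config(sphere_optimizee(2), opt, n_pop = 9L,
                             n_generations = 5L, seed = 3L)
    traj <- run_experiment(cfg)
    expect_true(all(vapply(traj$generations,
                           function(g) length(g$individuals), integer(1)) == 9L))
  }
})

test_that("unknown registry names fail with the registered list", {
  cfg <- experiment_config("no_such_optimizee", "ga", n_pop = 2L,
                           n_generations = 1L)
  expect_error(run_experiment(cfg), "registered.*ga|sphere")
  cfg2 <- experiment_config("sphere", "no_such_optimizer", n_pop = 2L,
                            n_generations = 1L)
  expect_error(run_experiment(cfg2), "unknown optimizer")
})

test_that("a YAML configuration drives a full run", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "experiment:",
    "  seed: 5",
    "  n_generations: 4",
    "  population: 8",
    "  workers: 1",
    "optimizee:",
    "  name: sphere",
    "  params:",
    "    dim: 2",
    "optimizer:",
    "  name: ga"), path)
  cfg <- read_experiment_config(path)
  expect_s3_class(cfg, "experiment_config")
  traj <- run_experiment(cfg)
  expect_length(traj$generations, 4)
})

test_that("the early-stop criterion halts a run", {
  optee <- list(spec = param_spec(x = list(low = 0, high = 1)),
                simulate = function(ind, seed) 1)
  cfg <- experiment_config(optee, optimizer_ga(), n_pop = 4L,
                           n_generations = 50L, seed = 1L, target_fitness = 0.5)
  traj <- run_experiment(cfg)
  expect_length(traj$generations, 1)
})

test_that("results_path persists the trajectory", {
  path <- withr::local_tempfile(fileext = ".json")
  cfg <- experiment_config("sphere", "ga", optimizee_params = list(dim = 2),
                           n_pop = 6L, n_generations = 3L, seed = 1L,
                           results_path = path)
  traj <- run_experiment(cfg)
  expect_equal(load_trajectory(path), traj)
})
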