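#' Configure a two-loop experiment
#'
#' Bundles everything a run needs: the optimizee (inner-loop simulation) and
#' optimizer (outer-loop algorithm), either as registered names or as
#' objects, population size, number of generations, fitness weights, worker
#' count, seed, and an optional results path for trajectory persistence.
#'
#' @param optimizee registered optimizee name, or an optimizee list
#'   (`spec`, `simulate`).
#' @param optimizer registered optimizer name, or an optimizer object.
#' @param optimizee_params,optimizer_params parameter lists handed to the
#'   registered factories when names are given.
#' @param n_pop population size (>= 1).
#' @param n_generations number of generations to run.
#' @param weights fitness weights; length must equal the optimizee's
#'   fitness-vector length.
#' @param n_workers parallel workers for generation evaluation.
#' @param seed experiment seed; with the configuration it fully determines
#'   the trajectory, including under parallel evaluation.
#' @param results_path optional file path; when set, the trajectory is
#'   persisted there at the end of the run.
#' @param target_fitness optional early-stop criterion: the run ends as soon
#'   as a scalar fitness >= this value has been observed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(optimizee, optimizer,
                              optimizee_params = list(),
                              optimizer_params = list(),
                              n_pop = 10L, n_generations = 10L,
                              weights = 1, n_workers = 1L, seed = 1L,
                              results_path = NULL, target_fitness = NULL) {
  if (n_pop < 1L) stop("n_pop must be >= 1", call. = FALSE)
  if (n_generations < 1L) stop("n_generations must be >= 1", call. = FALSE)
  structure(list(optimizee = optimizee, optimizer = optimizer,
                 optimizee_params = optimizee_params,
                 optimizer_params = optimizer_params,
                 n_pop = as.integer(n_pop),
                 n_generations = as.integer(n_generations),
                 weights = as.numeric(weights),
                 n_workers = as.integer(n_workers),
                 seed = as.integer(seed),
                 results_path = results_path,
                 target_fitness = target_fitness),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Expected layout: `experiment{name, seed, n_generations, population,
#' weights, workers, results_path, target_fitness}`, `optimizee{name,
#' params}`, `optimizer{name, params}`.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  ex <- y$experiment
  if (is.null(y$optimizee$name) || is.null(y$optimizer$name)) {
    stop("configuration must name an optimizee and an optimizer", call. = FALSE)
  }
  experiment_config(
    optimizee = y$optimizee$name, optimizer = y$optimizer$name,
    optimizee_params = if (is.null(y$optimizee$params)) list() else y$optimizee$params,
    optimizer_params = if (is.null(y$optimizer$params)) list() else y$optimizer$params,
    n_pop = if (is.null(ex$population)) 10L else ex$population,
    n_generations = if (is.null(ex$n_generations)) 10L else ex$n_generations,
    weights = if (is.null(ex$weights)) 1 else unlist(ex$weights),
    n_workers = if (is.null(ex$workers)) 1L else ex$workers,
    seed = if (is.null(ex$seed)) 1L else ex$seed,
    results_path = ex$results_path,
    target_fitness = ex$target_fitness)
}

.resolve_optimizee <- function(config) {
  if (is.character(config$optimizee)) {
    factory <- .registry_get("optimizee", config$optimizee)
    do.call(factory, list(config$optimizee_params))
  } else config$optimizee
}

.resolve_optimizer <- function(config) {
  if (is.character(config$optimizer)) {
    factory <- .registry_get("optimizer", config$optimizer)
    do.call(factory, list(config$optimizer_params))
  } else config$optimizer
}

#' Optimizer interface
#'
#' Every outer-loop algorithm implements two generics. `opt_init` builds the
#' initial population (and any internal state); `opt_step` maps one
#' evaluated generation to the next population. Both receive the parameter
#' spec so they can respect dimensionality; bound clipping is applied by
#' [run_experiment()] after every step.
#'
#' @param opt an optimizer object.
#' @param spec the optimizee's [param_spec()].
#' @param n_pop requested population size (grid search may override it).
#' @return `opt_init`: list with `population` (list of individuals) and
#'   `state`; `opt_step`: the same shape for the next generation.
#' @export
opt_init <- function(opt, spec, n_pop) UseMethod("opt_init")

#' @rdname opt_init
#' @param state optimizer state from the previous call.
#' @param population list of individuals just evaluated.
#' @param records matching list of fitness records.
#' @param generation index of the generation being bred (1-based).
#' @export
opt_step <- function(opt, state, population, records, spec, generation) {
  UseMethod("opt_step")
}

#' @export
opt_init.default <- function(opt, spec, n_pop) {
  population <- lapply(seq_len(n_pop) - 1L, function(i) {
    create_individual(spec, id = i, generation = 0L)
  })
  list(population = population, state = list())
}

#' Run a two-loop experiment
#'
#' The orchestration loop: evaluate the population (inner loop, optionally
#' parallel), record the generation in the trajectory, let the optimizer
#' breed the next population (outer loop), clip it to bounds, and repeat.
#' The trajectory is persisted to `config$results_path` when set.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-generation best fitness.
#' @return The completed [trajectory()].
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  optimizee <- .resolve_optimizee(config)
  optimizer <- .resolve_optimizer(config)
  spec <- optimizee$spec
  stopifnot(inherits(spec, "param_spec"))

  set.seed(derive_seed(config$seed, 0L, 1000003L))
  init <- opt_init(optimizer, spec, config$n_pop)
  population <- lapply(init$population, function(ind) apply_bounds(ind, spec))
  state <- init$state

  snapshot <- config
  snapshot$optimizee <- if (is.character(config$optimizee)) config$optimizee else "<inline>"
  snapshot$optimizer <- if (is.character(config$optimizer)) config$optimizer else "<inline>"
  traj <- trajectory(config = unclass(snapshot), seed = config$seed)

  n_gen <- config$n_generations
  for (g in seq_len(n_gen)) {
    records <- evaluate_generation(population, optimizee,
                                   weights = config$weights,
                                   n_workers = config$n_workers,
                                   experiment_seed = config$seed,
                                   generation = g - 1L)
    traj <- trajectory_append(traj, population, records)
    best <- max(vapply(records, `[[`, numeric(1), "scalar_fitness"))
    if (verbose) {
      message(sprintf("generation %d/%d: best fitness %.6g", g, n_gen, best))
    }
    if (!is.null(config$target_fitness) && best >= config$target_fitness) break
    if (g == n_gen) break
    set.seed(derive_seed(config$seed, g, 2000003L))
    stepped <- opt_step(optimizer, state, population, records, spec, g)
    state <- stepped$state
    population <- lapply(seq_along(stepped$population), function(i) {
      ind <- apply_bounds(stepped$population[[i]], spec)
      ind$id <- i - 1L
      ind$generation <- g
      ind
    })
  }
  if (!is.null(config$results_path)) persist_trajectory(traj, config$results_path)
  traj
}
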