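#' Scalarize a fitness vector with configured weights
#'
#' Multi-objective fitness vectors are reduced to the single value the
#' optimizers rank by: the dot product with the experiment's fitness
#' weights. A weight tuple of `c(1, 0.5)` counts the first objective fully
#' and the second at half strength.
#'
#' @param fv numeric fitness vector.
#' @param weights numeric weight vector of the same length.
#' @return The weighted (dot-product) scalar fitness.
#' @export
weighted_fitness <- function(fv, weights) {
  if (length(fv) != length(weights)) {
    stop(sprintf("fitness vector length %d does not match weights length %d",
                 length(fv), length(weights)), call. = FALSE)
  }
  sum(as.numeric(fv) * as.numeric(weights))
}

#' @rdname evaluate_generation
#' @param individual_id,fitness_vector,scalar_fitness,seed,failed record fields.
#' @export
fitness_record <- function(individual_id, fitness_vector, scalar_fitness,
                           seed = NA_integer_, failed = FALSE) {
  structure(list(individual_id = as.integer(individual_id),
                 fitness_vector = as.numeric(fitness_vector),
                 scalar_fitness = as.numeric(scalar_fitness),
                 seed = as.integer(seed), failed = isTRUE(failed)),
            class = "fitness_record")
}

#' Derive the per-evaluation RNG seed
#'
#' Each evaluation gets its own seed, hashed from (experiment seed,
#' generation, individual id) with a multiplicative congruential mix over
#' the Mersenne prime 2^31 - 1. This makes serial and parallel runs of the
#' same experiment bit-identical.
#'
#' @param experiment_seed,generation,individual_id integers.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(experiment_seed, generation, individual_id) {
  m <- 2147483647
  h <- (abs(as.numeric(experiment_seed)) %% m)
  h <- ((h + 1) * 48271) %% m
  h <- ((h + as.numeric(generation) %% m) * 48271) %% m
  h <- ((h + as.numeric(individual_id) %% m) * 48271) %% m
  as.integer(h %% (m - 1) + 1)
}

#' Evaluate one generation of individuals, optionally in parallel
#'
#' Runs the optimizee's `simulate` function once per individual. Each
#' evaluation is independent and receives a seed derived from
#' (experiment seed, generation, individual id), so results are identical
#' for `n_workers = 1` and `n_workers > 1`. An evaluation that raises an
#' error is kept (population size is preserved) but flagged failed with
#' scalar fitness `-Inf`; if every evaluation fails, the generation aborts.
#'
#' @param individuals list of individuals.
#' @param optimizee list with a `simulate(individual, seed)` function
#'   returning a numeric fitness vector.
#' @param weights fitness weights used for scalarization.
#' @param n_workers number of parallel worker processes (forked).
#' @param experiment_seed,generation inputs to the per-evaluation seed.
#' @return List of `fitness_record`s, order-aligned with `individuals`.
#' @export
evaluate_generation <- function(individuals, optimizee, weights = 1,
                                n_workers = 1L, experiment_seed = 0L,
                                generation = 0L) {
  stopifnot(length(individuals) >= 1L, is.function(optimizee$simulate))
  eval_one <- function(i) {
    ind <- individuals[[i]]
    seed <- derive_seed(experiment_seed, generation, ind$id)
    fv <- tryCatch({
      set.seed(seed)
      as.numeric(optimizee$simulate(ind, seed))
    }, error = function(e) structure(conditionMessage(e), class = "eval_failure"))
    if (inherits(fv, "eval_failure")) {
      fitness_record(ind$id, rep(-Inf, length(weights)), -Inf,
                     seed = seed, failed = TRUE)
    } else {
      fitness_record(ind$id, fv, weighted_fitness(fv, weights), seed = seed)
    }
  }
  idx <- seq_along(individuals)
  records <- if (n_workers > 1L) {
    parallel::mclapply(idx, eval_one, mc.cores = n_workers, mc.set.seed = FALSE)
  } else {
    lapply(idx, eval_one)
  }
  # mclapply returns error objects on worker-level failure; treat like a raise
  for (i in idx) {
    if (inherits(records[[i]], "try-error") || !inherits(records[[i]], "fitness_record")) {
      records[[i]] <- fitness_record(individuals[[i]]$id,
                                     rep(-Inf, length(weights)), -Inf,
                                     failed = TRUE)
    }
  }
  if (all(vapply(records, `[[`, logical(1), "failed"))) {
    stop("all evaluations in the generation failed", call. = FALSE)
  }
  records
}
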