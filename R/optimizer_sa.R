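#' Simulated-annealing acceptance and cooling schedules
#'
#' `sa_accept` applies the Metropolis rule under maximization: a candidate
#' at least as fit as the current solution is always accepted; a worse one
#' with probability `exp((f_cand - f_curr) / temperature)`. `sa_cooling`
#' maps a generation index to a temperature under one of three schedules:
#' exponential `T0 * cooling_factor^t`, linear
#' `T0 * max(0, 1 - t/n_generations)` (floored at a small positive value),
#' or logarithmic `T0 / log(t + e)`. The cooling factor sets the balance
#' between exploration (slow cooling) and exploitation (fast cooling).
#'
#' @param current_fitness,candidate_fitness scalar fitnesses.
#' @param temperature current temperature, > 0.
#' @return `sa_accept`: `TRUE` if the candidate is accepted.
#' @export
sa_accept <- function(current_fitness, candidate_fitness, temperature) {
  stopifnot(temperature > 0)
  delta <- candidate_fitness - current_fitness
  if (delta >= 0) return(TRUE)
  runif(1) < exp(delta / temperature)
}

#' @rdname sa_accept
#' @param generation 0-based generation index.
#' @param config an [sa_config()].
#' @export
sa_cooling <- function(generation, config) {
  t0 <- config$initial_temperature
  switch(config$schedule,
    exponential = t0 * config$cooling_factor^generation,
    linear = max(t0 * (1 - generation / config$n_generations), t0 * 1e-6),
    logarithmic = t0 / log(generation + exp(1)))
}

#' Simulated-annealing configuration and optimizer
#'
#' The population-based variant runs `n_pop` independent annealing chains:
#' each individual proposes a Gaussian perturbation of its chain's current
#' solution, and [sa_accept()] decides chain by chain.
#'
#' @param schedule `"exponential"`, `"linear"` or `"logarithmic"`.
#' @param initial_temperature starting temperature, > 0.
#' @param cooling_factor per-generation multiplier of the exponential
#'   schedule, in (0, 1).
#' @param step_sigma proposal standard deviation as a fraction of each
#'   parameter's declared range.
#' @param n_generations horizon used by the linear schedule.
#' @return `sa_config`: a config list; `optimizer_sa`: an optimizer object.
#' @export
sa_config <- function(schedule = c("exponential", "linear", "logarithmic"),
                      initial_temperature = 1, cooling_factor = 0.98,
                      step_sigma = 0.1, n_generations = 100L) {
  schedule <- match.arg(schedule)
  if (initial_temperature <= 0) stop("initial temperature must be > 0", call. = FALSE)
  stopifnot(cooling_factor > 0, cooling_factor < 1, step_sigma > 0)
  structure(list(schedule = schedule, initial_temperature = initial_temperature,
                 cooling_factor = cooling_factor, step_sigma = step_sigma,
                 n_generations = as.integer(n_generations)),
            class = "sa_config")
}

#' @rdname sa_config
#' @param ... arguments passed to `sa_config`.
#' @export
optimizer_sa <- function(...) {
  structure(list(config = do.call(sa_config, list(...))),
            class = c("optimizer_sa", "optimizer"))
}

#' @export
opt_init.optimizer_sa <- function(opt, spec, n_pop) {
  init <- NextMethod()
  m <- population_matrix(init$population, spec)
  init$state <- list(current = m, current_fitness = rep(-Inf, n_pop))
  init
}

#' @export
opt_step.optimizer_sa <- function(opt, state, population, records, spec, generation) {
  cfg <- opt$config
  fs <- vapply(records, `[[`, numeric(1), "scalar_fitness")
  cand <- population_matrix(population, spec)
  temp <- sa_cooling(generation - 1L, cfg)
  for (i in seq_len(nrow(cand))) {
    if (sa_accept(state$current_fitness[i], fs[i], temp)) {
      state$current[i, ] <- cand[i, ]
      state$current_fitness[i] <- fs[i]
    }
  }
  ranges <- unlist(lapply(spec$entries, function(e) rep(e$high - e$low, e$shape)))
  proposal <- state$current +
    matrix(rnorm(length(state$current), sd = cfg$step_sigma * rep(ranges, each = nrow(cand))),
           nrow = nrow(cand))
  list(state = state, population = matrix_population(proposal, spec, generation))
}
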