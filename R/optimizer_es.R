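#' Evolution-strategies step (stochastic search-gradient ascent)
#'
#' Offspring are Gaussian perturbations `center + sigma * eps_i` of a
#' search center. The fitness of each offspring is rank-standardized (ties
#' averaged, zero mean, unit variance) and the center moves along the
#' fitness-weighted average of the perturbations:
#' `center <- center + learning_rate / (n * sigma) * sum(f_std_i * eps_i)`.
#' When all offspring score equally the standardized fitness is identically
#' zero and the center is unchanged.
#'
#' @param center numeric parameter vector.
#' @param offspring_fitnesses numeric vector of offspring fitnesses.
#' @param noises `n x d` matrix of the recorded perturbations `eps_i`.
#' @param config an [es_config()].
#' @return The updated center.
#' @export
es_step <- function(center, offspring_fitnesses, noises, config) {
  noises <- as.matrix(noises)
  n <- nrow(noises)
  stopifnot(length(offspring_fitnesses) == n, length(center) == ncol(noises))
  r <- rank(offspring_fitnesses, ties.method = "average")
  s <- sd(r)
  f_std <- if (is.na(s) || s == 0) rep(0, n) else (r - mean(r)) / s
  grad <- colSums(noises * f_std) / (n * config$sigma)
  center + config$learning_rate * grad
}

#' Evolution-strategies configuration and optimizer
#' @param sigma perturbation scale, > 0.
#' @param learning_rate step size for the center update.
#' @param n_offspring offspring per generation (population size).
#' @return `es_config`: a config list; `optimizer_es`: an optimizer object.
#' @export
es_config <- function(sigma = 0.1, learning_rate = 0.1, n_offspring = 20L) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  stopifnot(learning_rate > 0, n_offspring >= 2L)
  structure(list(sigma = sigma, learning_rate = learning_rate,
                 n_offspring = as.integer(n_offspring)), class = "es_config")
}

#' @rdname es_config
#' @param ... arguments passed to `es_config`.
#' @export
optimizer_es <- function(...) {
  structure(list(config = do.call(es_config, list(...))),
            class = c("optimizer_es", "optimizer"))
}

.es_sample <- function(center, config, spec, generation) {
  d <- length(center)
  noises <- matrix(rnorm(config$n_offspring * d), nrow = config$n_offspring)
  pop <- matrix_population(sweep(noises * config$sigma, 2L, center, `+`),
                           spec, generation)
  list(population = pop, noises = noises)
}

#' @export
opt_init.optimizer_es <- function(opt, spec, n_pop) {
  center <- unname(flatten_individual(create_individual(spec), spec))
  s <- .es_sample(center, opt$config, spec, 0L)
  list(population = s$population,
       state = list(center = center, noises = s$noises))
}

#' @export
opt_step.optimizer_es <- function(opt, state, population, records, spec, generation) {
  fs <- vapply(records, `[[`, numeric(1), "scalar_fitness")
  center <- es_step(state$center, fs, state$noises, opt$config)
  s <- .es_sample(center, opt$config, spec, generation)
  list(state = list(center = center, noises = s$noises), population = s$population)
}
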