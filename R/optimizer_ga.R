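#' Hall of Fame: elitist archive of the best individuals ever seen
#'
#' Keeps the `capacity` highest-fitness individuals over the whole run,
#' sorted descending by scalar fitness; its best entry is therefore
#' non-decreasing over generations.
#'
#' @param capacity maximum number of archived individuals, >= 1.
#' @return An object of class `hall_of_fame`.
#' @export
hall_of_fame <- function(capacity = 1L) {
  stopifnot(capacity >= 1L)
  structure(list(capacity = as.integer(capacity),
                 individuals = list(), fitnesses = numeric(0)),
            class = "hall_of_fame")
}

#' @rdname hall_of_fame
#' @param hof a `hall_of_fame`.
#' @param individuals candidate individuals.
#' @param fitnesses their scalar fitnesses.
#' @export
hof_update <- function(hof, individuals, fitnesses) {
  stopifnot(inherits(hof, "hall_of_fame"), length(individuals) == length(fitnesses))
  inds <- c(hof$individuals, individuals)
  fs <- c(hof$fitnesses, as.numeric(fitnesses))
  keep <- order(fs, decreasing = TRUE)[seq_len(min(length(fs), hof$capacity))]
  hof$individuals <- inds[keep]
  hof$fitnesses <- fs[keep]
  hof
}

#' @rdname hall_of_fame
#' @export
hof_best <- function(hof) {
  if (length(hof$fitnesses) == 0L) return(list(individual = NULL, fitness = -Inf))
  list(individual = hof$individuals[[1L]], fitness = hof$fitnesses[1L])
}

#' One genetic-algorithm generation
#'
#' Tournament selection (with replacement) chooses parents; consecutive
#' parent pairs undergo blend (BLX-alpha) crossover with probability
#' `crossover_prob`; each offspring is then Gaussian-mutated (every gene
#' perturbed with standard deviation `mutation_sigma`, expressed as a
#' fraction of the parameter range) with probability `mutation_prob`. The
#' Hall of Fame is updated with the evaluated parents before breeding, so
#' the best solution ever seen is never lost.
#'
#' @param population list of evaluated individuals.
#' @param fitnesses their scalar fitnesses.
#' @param config a [ga_config()].
#' @param hof a [hall_of_fame()]; updated and returned.
#' @param spec the [param_spec()] (used for mutation scaling).
#' @return List with `population` (same size as the input) and `hof`.
#' @export
ga_step <- function(population, fitnesses, config, hof, spec) {
  n <- length(population)
  stopifnot(n >= config$tournament_size)
  hof <- hof_update(hof, population, fitnesses)
  m <- population_matrix(population, spec)
  ranges <- unlist(lapply(spec$entries, function(e) rep(e$high - e$low, e$shape)))

  tournament <- function() {
    contenders <- sample.int(n, config$tournament_size, replace = TRUE)
    contenders[which.max(fitnesses[contenders])]
  }
  parents <- vapply(seq_len(n), function(i) tournament(), integer(1))
  off <- m[parents, , drop = FALSE]

  alpha <- config$blend_alpha
  for (i in seq_len(n %/% 2L)) {
    a <- 2L * i - 1L; b <- 2L * i
    if (runif(1) < config$crossover_prob) {
      p1 <- off[a, ]; p2 <- off[b, ]
      lo <- pmin(p1, p2) - alpha * abs(p1 - p2)
      hi <- pmax(p1, p2) + alpha * abs(p1 - p2)
      off[a, ] <- runif(ncol(off), lo, hi)
      off[b, ] <- runif(ncol(off), lo, hi)
    }
  }
  for (i in seq_len(n)) {
    if (runif(1) < config$mutation_prob) {
      off[i, ] <- off[i, ] + rnorm(ncol(off), sd = config$mutation_sigma * ranges)
    }
  }
  list(population = matrix_population(off, spec), hof = hof)
}

#' Genetic-algorithm configuration
#'
#' @param tournament_size number of contenders per selection, >= 2.
#' @param crossover_prob probability a parent pair is blended.
#' @param mutation_prob probability an offspring is mutated.
#' @param mutation_sigma mutation standard deviation as a fraction of each
#'   parameter's declared range.
#' @param blend_alpha BLX-alpha expansion factor for crossover.
#' @param hof_size Hall of Fame capacity.
#' @return A `ga_config` list.
#' @export
ga_config <- function(tournament_size = 3L, crossover_prob = 0.7,
                      mutation_prob = 0.3, mutation_sigma = 0.1,
                      blend_alpha = 0.5, hof_size = 5L) {
  stopifnot(tournament_size >= 2L,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            mutation_sigma >= 0, hof_size >= 1L)
  structure(list(tournament_size = as.integer(tournament_size),
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 mutation_sigma = mutation_sigma, blend_alpha = blend_alpha,
                 hof_size = as.integer(hof_size)),
            class = "ga_config")
}

#' Genetic-algorithm optimizer
#'
#' Registry wrapper around [ga_step()] for use with [run_experiment()].
#' @param ... arguments passed to [ga_config()].
#' @return An optimizer object.
#' @export
optimizer_ga <- function(...) {
  structure(list(config = ga_config(...)), class = c("optimizer_ga", "optimizer"))
}

#' @export
opt_init.optimizer_ga <- function(opt, spec, n_pop) {
  init <- NextMethod()
  init$state <- list(hof = hall_of_fame(opt$config$hof_size))
  init
}

#' @export
opt_step.optimizer_ga <- function(opt, state, population, records, spec, generation) {
  fs <- vapply(records, `[[`, numeric(1), "scalar_fitness")
  stepped <- ga_step(population, fs, opt$config, state$hof, spec)
  list(state = list(hof = stepped$hof), population = stepped$population)
}
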