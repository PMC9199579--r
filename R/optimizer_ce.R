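#' Cross-entropy method step
#'
#' The top `elite_fraction` of the population by fitness is selected and a
#' Gaussian distribution is refit to the elites, smoothed toward the
#' previous distribution parameters
#' (`new = smoothing * old + (1 - smoothing) * elite_fit`). A degenerate
#' elite covariance is regularized by adding a small diagonal floor. The
#' next population is sampled from the refit distribution.
#'
#' @param population_matrix `n x d` matrix of evaluated individuals.
#' @param fitnesses their scalar fitnesses.
#' @param config a [ce_config()].
#' @param prev optional list `(mean, cov)` from the previous generation.
#' @return List with `mean`, `cov` and `population` (`n x d` sample).
#' @export
ce_step <- function(population_matrix, fitnesses, config, prev = NULL) {
  m <- as.matrix(population_matrix)
  n <- nrow(m)
  stopifnot(length(fitnesses) == n)
  k <- max(2L, ceiling(config$elite_fraction * n))
  if (k > n) k <- n
  elites <- m[order(fitnesses, decreasing = TRUE)[seq_len(k)], , drop = FALSE]
  mu <- colMeans(elites)
  sigma <- cov(elites) * (k - 1) / k
  sigma <- sigma + diag(config$cov_floor, ncol(m))
  if (!is.null(prev)) {
    mu <- config$smoothing * prev$mean + (1 - config$smoothing) * mu
    sigma <- config$smoothing * prev$cov + (1 - config$smoothing) * sigma
  }
  pop <- MASS::mvrnorm(n, mu = mu, Sigma = sigma)
  if (n == 1L) pop <- matrix(pop, nrow = 1L)
  list(mean = mu, cov = sigma, population = pop)
}

#' Cross-entropy configuration and optimizer
#' @param elite_fraction fraction of the population refit, in (0, 1].
#' @param smoothing weight of the previous distribution in the refit.
#' @param cov_floor diagonal floor added to the elite covariance.
#' @return `ce_config`: a config list; `optimizer_ce`: an optimizer object.
#' @export
ce_config <- function(elite_fraction = 0.2, smoothing = 0.3, cov_floor = 1e-8) {
  stopifnot(elite_fraction > 0, elite_fraction <= 1,
            smoothing >= 0, smoothing < 1, cov_floor >= 0)
  structure(list(elite_fraction = elite_fraction, smoothing = smoothing,
                 cov_floor = cov_floor), class = "ce_config")
}

#' @rdname ce_config
#' @param ... arguments passed to `ce_config`.
#' @export
optimizer_ce <- function(...) {
  structure(list(config = do.call(ce_config, list(...))),
            class = c("optimizer_ce", "optimizer"))
}

#' @export
opt_step.optimizer_ce <- function(opt, state, population, records, spec, generation) {
  fs <- vapply(records, `[[`, numeric(1), "scalar_fitness")
  m <- population_matrix(population, spec)
  stepped <- ce_step(m, fs, opt$config, prev = state$dist)
  list(state = list(dist = stepped[c("mean", "cov")]),
       population = matrix_population(stepped$population, spec, generation))
}
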