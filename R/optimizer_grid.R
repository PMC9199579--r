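#' Exhaustive grid search population
#'
#' Generates the Cartesian product of evenly spaced values (both endpoints
#' included) over every scalar dimension of the spec. Brute force: useful
#' for small parameter spaces and as the dense-grid oracle other
#' optimizers are checked against. The combination count grows as
#' `resolution^dimension`; a configurable cap guards against accidental
#' combinatorial explosions and the error reports the offending count.
#'
#' @param spec a [param_spec()].
#' @param resolution points per dimension: a single integer or one per
#'   scalar dimension.
#' @param max_combinations cap on the total number of combinations.
#' @return List of individuals covering the grid.
#' @export
grid_generate <- function(spec, resolution, max_combinations = 1e6) {
  stopifnot(inherits(spec, "param_spec"))
  d <- spec_dimension(spec)
  resolution <- as.integer(resolution)
  if (length(resolution) == 1L) resolution <- rep(resolution, d)
  stopifnot(length(resolution) == d, all(resolution >= 1L))
  log10_count <- sum(log10(resolution))
  if (log10_count > log10(max_combinations)) {
    stop(sprintf(
      "grid of %s combinations (~10^%.1f) exceeds the cap of %g",
      paste0(resolution[1L], "^", d), log10_count, max_combinations),
      call. = FALSE)
  }
  low <- unlist(lapply(spec$entries, function(e) rep(e$low, e$shape)))
  high <- unlist(lapply(spec$entries, function(e) rep(e$high, e$shape)))
  axes <- lapply(seq_len(d), function(j) {
    if (resolution[j] == 1L) mean(c(low[j], high[j]))
    else seq(low[j], high[j], length.out = resolution[j])
  })
  pts <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- NULL
  matrix_population(pts, spec, 0L)
}

#' Grid-search optimizer
#'
#' Evaluates the full grid as its (single) generation; subsequent steps
#' return the same population unchanged, so the run is effectively one
#' exhaustive evaluation. The population size is defined by the grid, not
#' by `n_pop`.
#'
#' @param resolution points per dimension (see [grid_generate()]).
#' @param max_combinations combination cap.
#' @return An optimizer object.
#' @export
optimizer_grid <- function(resolution = 10L, max_combinations = 1e6) {
  structure(list(resolution = resolution, max_combinations = max_combinations),
            class = c("optimizer_grid", "optimizer"))
}

#' @export
opt_init.optimizer_grid <- function(opt, spec, n_pop) {
  pop <- grid_generate(spec, opt$resolution, opt$max_combinations)
  list(population = pop, state = list())
}

#' @export
opt_step.optimizer_grid <- function(opt, state, population, records, spec, generation) {
  list(state = state, population = population)
}
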