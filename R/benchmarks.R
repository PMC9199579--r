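#' Standard benchmark surfaces for the optimizers
#'
#' Negated classic test functions (maximization convention): the sphere
#' `-sum(x^2)` and the Rastrigin function
#' `-(10 d + sum(x^2 - 10 cos(2 pi x)))`. Both have their global optimum
#' 0 at the origin.
#'
#' @param name `"sphere"` or `"rastrigin"`.
#' @param x numeric parameter vector.
#' @return The (negated) function value.
#' @export
benchmark_function <- function(name, x) {
  switch(name,
    sphere = -sum(x^2),
    rastrigin = -(10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))),
    stop("unknown benchmark function: ", name, call. = FALSE))
}

#' Benchmark optimizee factory
#'
#' @param params list with `name` (benchmark name), `dim` (dimension,
#'   default 2) and `low`/`high` bounds (default `[-5, 5]`).
#' @return An optimizee (spec + simulate) for [run_experiment()].
#' @export
benchmark_optimizee <- function(params = list()) {
  name <- if (is.null(params$name)) "sphere" else params$name
  dim <- if (is.null(params$dim)) 2L else as.integer(params$dim)
  low <- if (is.null(params$low)) -5 else params$low
  high <- if (is.null(params$high)) 5 else params$high
  benchmark_function(name, rep(0, dim))  # fail fast on unknown names
  list(
    spec = param_spec(x = list(shape = dim, low = low, high = high)),
    simulate = function(ind, seed) benchmark_function(name, ind$values$x))
}
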