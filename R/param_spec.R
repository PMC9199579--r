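#' Declare the parameter space of an optimizee
#'
#' A parameter specification lists the named parameter blocks an individual
#' carries, with per-block length, bounds, and kind. It is the single source
#' of truth for sampling new individuals ([create_individual()]) and for
#' clipping them back into range ([apply_bounds()]).
#'
#' @param ... named arguments, one per parameter block. Each is a list with
#'   elements `shape` (positive integer, default 1), `low`, `high`
#'   (finite, `low < high`) and optionally `kind` (`"continuous"`, the
#'   default, or `"integer"`).
#' @return An object of class `param_spec`.
#' @examples
#' spec <- param_spec(w = list(shape = 3, low = -1, high = 1),
#'                    d = list(shape = 3, low = 1, high = 6, kind = "integer"))
#' @export
param_spec <- function(...) {
  entries <- list(...)
  if (length(entries) == 0L) stop("empty parameter spec", call. = FALSE)
  nms <- names(entries)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
    stop("parameter spec entries must have unique names", call. = FALSE)
  }
  entries <- lapply(entries, function(e) {
    e$shape <- if (is.null(e$shape)) 1L else as.integer(e$shape)
    e$kind <- if (is.null(e$kind)) "continuous" else match.arg(e$kind, c("continuous", "integer"))
    if (e$shape < 1L) stop("shape must be a positive integer", call. = FALSE)
    if (!is.finite(e$low) || !is.finite(e$high) || e$low >= e$high) {
      stop("bounds must be finite with low < high", call. = FALSE)
    }
    e[c("shape", "low", "high", "kind")]
  })
  structure(list(entries = entries), class = "param_spec")
}

#' @export
print.param_spec <- function(x, ...) {
  cat("<param_spec>", spec_dimension(x), "dimensions\n")
  for (nm in names(x$entries)) {
    e <- x$entries[[nm]]
    cat(sprintf("  %s: %d x [%g, %g] (%s)\n", nm, e$shape, e$low, e$high, e$kind))
  }
  invisible(x)
}

#' Total dimensionality of a parameter spec
#' @param spec a [param_spec()].
#' @return Integer, the sum of all block shapes.
#' @export
spec_dimension <- function(spec) {
  stopifnot(inherits(spec, "param_spec"))
  sum(vapply(spec$entries, `[[`, integer(1), "shape"))
}

#' Sample a new individual uniformly within its declared bounds
#'
#' An individual is the unit the optimizers move: a named list of numeric
#' parameter vectors plus bookkeeping (`id`, `generation`). Continuous
#' blocks are sampled uniformly on `[low, high]`; integer blocks uniformly
#' on the integers of that range. Deterministic given the R RNG state.
#'
#' @param spec a [param_spec()].
#' @param id integer identifier within the population.
#' @param generation generation index (0 for the initial population).
#' @return An object of class `individual`.
#' @export
create_individual <- function(spec, id = 0L, generation = 0L) {
  stopifnot(inherits(spec, "param_spec"))
  values <- lapply(spec$entries, function(e) {
    if (e$kind == "integer") {
      as.numeric(sample(seq.int(ceiling(e$low), floor(e$high)), e$shape, replace = TRUE))
    } else {
      runif(e$shape, e$low, e$high)
    }
  })
  new_individual(values, id = id, generation = generation)
}

#' @rdname create_individual
#' @param values named list of numeric parameter vectors.
#' @export
new_individual <- function(values, id = 0L, generation = 0L) {
  structure(list(values = values, id = as.integer(id),
                 generation = as.integer(generation)),
            class = "individual")
}

#' @export
print.individual <- function(x, ...) {
  cat(sprintf("<individual #%d, generation %d>\n", x$id, x$generation))
  utils::str(x$values, give.attr = FALSE)
  invisible(x)
}

#' Clip an individual's parameters to their declared ranges
#'
#' Applied after every optimizer step (and available to optimizees before
#' simulation), mirroring the bounding function of the optimizee contract.
#' Continuous blocks are clamped elementwise to `[low, high]`; integer
#' blocks are rounded to the nearest integer and then clamped. Idempotent.
#'
#' @param ind an `individual`.
#' @param spec the matching [param_spec()].
#' @return The clipped individual.
#' @export
apply_bounds <- function(ind, spec) {
  stopifnot(inherits(ind, "individual"), inherits(spec, "param_spec"))
  if (!identical(sort(names(ind$values)), sort(names(spec$entries)))) {
    stop("individual parameter names do not match the spec", call. = FALSE)
  }
  ind$values <- lapply(setNames(nm = names(spec$entries)), function(nm) {
    e <- spec$entries[[nm]]
    v <- ind$values[[nm]]
    if (e$kind == "integer") v <- round(v)
    pmin(pmax(v, e$low), e$high)
  })
  ind
}

#' Flatten an individual to a plain numeric vector (and back)
#'
#' The optimizers operate on flat vectors; these helpers define the stable
#' block order (the order of the spec entries) used throughout.
#'
#' @param ind an `individual`.
#' @param spec a [param_spec()].
#' @return `flatten_individual`: a named numeric vector.
#' @export
flatten_individual <- function(ind, spec) {
  unlist(ind$values[names(spec$entries)], use.names = TRUE)
}

#' @rdname flatten_individual
#' @param x numeric vector of length [spec_dimension()].
#' @param id,generation bookkeeping for the rebuilt individual.
#' @export
unflatten_individual <- function(x, spec, id = 0L, generation = 0L) {
  shapes <- vapply(spec$entries, `[[`, integer(1), "shape")
  stopifnot(length(x) == sum(shapes))
  idx <- cumsum(shapes)
  values <- Map(function(from, to) unname(x[from:to]),
                c(1L, head(idx, -1L) + 1L), idx)
  names(values) <- names(spec$entries)
  new_individual(values, id = id, generation = generation)
}

#' Population matrix helpers
#'
#' Convert between a list of individuals and an `n_pop x d` matrix in the
#' spec's stable block order.
#' @param pop list of individuals.
#' @param spec a [param_spec()].
#' @return `population_matrix`: numeric matrix, one row per individual.
#' @export
population_matrix <- function(pop, spec) {
  do.call(rbind, lapply(pop, function(ind) unname(flatten_individual(ind, spec))))
}

#' @rdname population_matrix
#' @param m numeric matrix, one row per individual.
#' @param generation generation stamp for the rebuilt individuals.
#' @export
matrix_population <- function(m, spec, generation = 0L) {
  lapply(seq_len(nrow(m)), function(i) {
    unflatten_individual(m[i, ], spec, id = i - 1L, generation = generation)
  })
}
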