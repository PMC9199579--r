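#' Gradient-ascent step from probe evaluations
#'
#' The gradient of the (black-box) fitness surface at the center is
#' estimated by a least-squares regression of the probe fitnesses on the
#' probe offsets; for a noise-free linear fitness this recovers the exact
#' gradient. With fewer probes than dimensions the rank-deficient system is
#' solved in the least-norm sense (Moore-Penrose pseudoinverse). The center
#' then moves `learning_rate` along the estimate.
#'
#' @param center numeric parameter vector.
#' @param probes `n_probe x d` matrix of probe locations around the center.
#' @param probe_fitnesses fitness of each probe.
#' @param config a [gd_config()].
#' @return The updated center.
#' @export
gradient_step <- function(center, probes, probe_fitnesses, config) {
  probes <- as.matrix(probes)
  stopifnot(ncol(probes) == length(center),
            nrow(probes) == length(probe_fitnesses))
  # center both sides so the (unknown) intercept drops out exactly
  x <- sweep(probes, 2L, colMeans(probes))
  y <- probe_fitnesses - mean(probe_fitnesses)
  g <- as.numeric(MASS::ginv(x) %*% y)
  center + config$learning_rate * g
}

#' Gradient-ascent configuration and optimizer
#'
#' @param learning_rate step size along the estimated gradient.
#' @param n_probe probes per generation (`mode = "single"`).
#' @param probe_scale standard deviation of probe offsets.
#' @param mode `"single"` (one center, [gradient_step()]) or `"multi"`
#'   (several centers with clouds, [multi_gradient_step()]).
#' @param n_individuals,cloud_size multi-mode: number of centers and
#'   parameter combinations per center.
#' @param shrink_factor multi-mode: per-generation contraction of each
#'   cloud's range.
#' @return `gd_config`: a config list; `optimizer_gd`: an optimizer object.
#' @export
gd_config <- function(learning_rate = 0.01, n_probe = 10L, probe_scale = 0.1,
                      mode = c("single", "multi"), n_individuals = 4L,
                      cloud_size = 64L, shrink_factor = 0.9) {
  mode <- match.arg(mode)
  stopifnot(learning_rate >= 0, n_probe >= 2L, probe_scale > 0,
            n_individuals >= 1L, cloud_size >= 1L,
            shrink_factor > 0, shrink_factor <= 1)
  structure(list(learning_rate = learning_rate, n_probe = as.integer(n_probe),
                 probe_scale = probe_scale, mode = mode,
                 n_individuals = as.integer(n_individuals),
                 cloud_size = as.integer(cloud_size),
                 shrink_factor = shrink_factor),
            class = "gd_config")
}

#' @rdname gd_config
#' @param ... arguments passed to `gd_config`.
#' @export
optimizer_gd <- function(...) {
  structure(list(config = do.call(gd_config, list(...))),
            class = c("optimizer_gd", "optimizer"))
}

#' Multi-gradient ascent over per-individual parameter clouds
#'
#' Each of several individuals carries a cloud of parameter combinations
#' evaluated in one batch (the expanded form: every fitness is linked to
#' the combination that produced it). Per individual, the best-scoring
#' combination becomes the new center, nudged further along the direction
#' of improvement by `learning_rate`; a fresh cloud (an evenly spaced grid)
#' is generated around it with the per-dimension half-range contracted by
#' `shrink_factor`. The compressed result contains only the new parameter
#' combinations.
#'
#' @param clouds list (one entry per individual) of lists with elements
#'   `center` (numeric vector), `half_range` (per-dimension half width) and
#'   `points` (`cloud_size x d` matrix of evaluated combinations).
#' @param fitness_vectors list of numeric vectors, one fitness per point.
#' @param config a [gd_config()] with `mode = "multi"`.
#' @param bounds optional list `(low, high)` of per-dimension vectors the
#'   new clouds are clipped to.
#' @return List of updated clouds (same length, same `points` shape).
#' @export
multi_gradient_step <- function(clouds, fitness_vectors, config, bounds = NULL) {
  stopifnot(length(clouds) == length(fitness_vectors))
  lapply(seq_along(clouds), function(i) {
    cloud <- clouds[[i]]
    fs <- fitness_vectors[[i]]
    if (is.null(cloud$points) || nrow(cloud$points) == 0L) {
      stop("empty parameter cloud", call. = FALSE)
    }
    stopifnot(nrow(cloud$points) == length(fs))
    best <- cloud$points[which.max(fs), ]
    center <- best + config$learning_rate * (best - cloud$center)
    half_range <- cloud$half_range * config$shrink_factor
    if (!is.null(bounds)) {
      center <- pmin(pmax(center, bounds$low), bounds$high)
    }
    make_cloud(center, half_range, nrow(cloud$points), bounds = bounds)
  })
}

#' Build an evenly spaced parameter cloud around a center
#'
#' The cloud is a Cartesian grid with (approximately) `n_points`
#' combinations: per-dimension resolution `ceiling(n_points^(1/d))`,
#' truncated back to `n_points` rows.
#'
#' @param center numeric vector.
#' @param half_range per-dimension half width of the grid.
#' @param n_points requested number of combinations.
#' @param bounds optional `(low, high)` clipping for the grid coordinates.
#' @return A cloud list (`center`, `half_range`, `points`).
#' @export
make_cloud <- function(center, half_range, n_points, bounds = NULL) {
  d <- length(center)
  res <- max(2L, as.integer(ceiling(n_points^(1 / d))))
  axes <- lapply(seq_len(d), function(j) {
    ax <- seq(center[j] - half_range[j], center[j] + half_range[j], length.out = res)
    if (!is.null(bounds)) ax <- pmin(pmax(ax, bounds$low[j]), bounds$high[j])
    ax
  })
  pts <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- NULL
  if (nrow(pts) > n_points) pts <- pts[seq_len(n_points), , drop = FALSE]
  list(center = center, half_range = half_range, points = pts)
}

#' @export
opt_init.optimizer_gd <- function(opt, spec, n_pop) {
  center <- unname(flatten_individual(create_individual(spec), spec))
  cfg <- opt$config
  if (cfg$mode == "single") {
    probes <- sweep(matrix(rnorm(cfg$n_probe * length(center), sd = cfg$probe_scale),
                           nrow = cfg$n_probe), 2L, center, `+`)
    list(population = matrix_population(probes, spec, 0L),
         state = list(center = center, probes = probes))
  } else {
    stop("multi-gradient mode is driven through multi_gradient_step()/fit_fc()",
         call. = FALSE)
  }
}

#' @export
opt_step.optimizer_gd <- function(opt, state, population, records, spec, generation) {
  cfg <- opt$config
  fs <- vapply(records, `[[`, numeric(1), "scalar_fitness")
  center <- gradient_step(state$center, state$probes, fs, cfg)
  probes <- sweep(matrix(rnorm(cfg$n_probe * length(center), sd = cfg$probe_scale),
                         nrow = cfg$n_probe), 2L, center, `+`)
  list(state = list(center = center, probes = probes),
       population = matrix_population(probes, spec, generation))
}
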