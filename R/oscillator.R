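#' Simulate a coupled noisy limit-cycle oscillator network
#'
#' Surrogate for regional brain activity: each region is a noisy
#' Stuart-Landau oscillator whose first coordinate is coupled to the
#' delayed activity of the other regions through the structural
#' connectivity,
#' `dx_i = ((a - x_i^2 - y_i^2) x_i - omega_i y_i + coupling * sum_j SC_ij x_j(t - d_ij)) dt + noise`,
#' with conduction delays `d_ij = |i - j| / speed` (an index-distance
#' proxy, in ms). Euler integration; the region-wise `x` series is
#' returned for functional-connectivity analysis ([fc_sc_fitness()]).
#'
#' @param sc `n x n` nonnegative structural connectivity with zero
#'   diagonal.
#' @param coupling global coupling strength, >= 0.
#' @param speed conduction speed (index units per ms), > 0.
#' @param steps number of retained samples.
#' @param dt integration step (ms).
#' @param noise_sd per-step noise standard deviation.
#' @param a limit-cycle excitability parameter.
#' @param omega base angular frequency (rad/ms); per-region frequencies are
#'   dispersed +-40% around it so uncoupled regions decohere over the
#'   sampling window instead of staying phase-locked.
#' @param burn_in discarded initial steps.
#' @return `n x steps` matrix of regional activity.
#' @export
oscillator_network <- function(sc, coupling, speed, steps = 800L, dt = 0.1,
                               noise_sd = 0.2, a = 1, omega = 0.6,
                               burn_in = 200L) {
  sc <- as.matrix(sc)
  n <- nrow(sc)
  stopifnot(ncol(sc) == n, all(sc >= 0), coupling >= 0, speed > 0)
  dist <- abs(outer(seq_len(n), seq_len(n), `-`))
  delay_steps <- pmax(1L, round(dist / speed / dt))
  max_d <- max(delay_steps)
  total <- burn_in + steps
  omegas <- omega * (1 + 0.8 * (seq_len(n) - (n + 1) / 2) / n)

  # random phases on the limit cycle: uncoupled regions start decoherent
  theta <- runif(n, 0, 2 * pi)
  x <- sqrt(a) * cos(theta); y <- sqrt(a) * sin(theta)
  xh <- matrix(x, n, max_d)     # ring-buffer history of x for the delays
  out <- matrix(0, n, steps)
  jmat <- matrix(seq_len(n), n, n, byrow = TRUE)  # jmat[i, j] = j
  for (s in seq_len(total)) {
    col <- ((s - 1L) %% max_d) + 1L
    # delayed x_j for each pair (i, j): history column of step s - d_ij
    dcol <- ((s - 1L - delay_steps) %% max_d) + 1L
    xd <- matrix(xh[cbind(as.vector(jmat), as.vector(dcol))], n, n)
    inp <- coupling * rowSums(sc * xd)
    r2 <- x^2 + y^2
    dx <- (a - r2) * x - omegas * y + inp
    dy <- (a - r2) * y + omegas * x
    x <- x + dt * dx + rnorm(n, 0, noise_sd * sqrt(dt))
    y <- y + dt * dy + rnorm(n, 0, noise_sd * sqrt(dt))
    if (any(abs(x) > 1e3) || any(!is.finite(x))) {
      stop("oscillator network diverged", call. = FALSE)
    }
    xh[, col] <- x
    if (s > burn_in) out[, s - burn_in] <- x
  }
  out
}

#' Generate a modular structural connectivity matrix
#'
#' Block-modular SC fixture: strong within-module weights, weak
#' between-module weights, zero diagonal, symmetric, scaled to a maximum
#' of 1.
#'
#' @param n number of regions.
#' @param n_modules number of modules.
#' @param within,between mean connection strengths.
#' @return `n x n` numeric matrix.
#' @export
modular_sc <- function(n = 10L, n_modules = 2L, within = 1, between = 0.1) {
  module <- rep(seq_len(n_modules), length.out = n)
  base <- ifelse(outer(module, module, `==`), within, between)
  noise <- matrix(runif(n * n, 0.5, 1), n, n)
  sc <- base * (noise + t(noise)) / 2
  diag(sc) <- 0
  sc / max(sc)
}

#' Read / write a structural connectivity matrix as CSV
#' @param sc matrix (for writing).
#' @param path CSV file path.
#' @return `read_sc_csv`: the matrix.
#' @export
write_sc_csv <- function(sc, path) {
  write.csv(as.data.frame(sc), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sc_csv
#' @export
read_sc_csv <- function(path) {
  as.matrix(read.csv(path))
}

#' Fit oscillator coupling and speed to structural connectivity
#'
#' Multi-gradient ascent over `(coupling, speed)`: several individuals
#' each carry a grid cloud of parameter combinations, every combination is
#' simulated and scored with [fc_sc_fitness()] (the expanded form: one
#' fitness per combination), and [multi_gradient_step()] re-centers each
#' cloud on its best combination. Simulations use a fixed seed derived
#' from `seed`, so the fitness surface is deterministic and comparable to
#' a dense-grid oracle over the same ranges.
#'
#' @param sc structural connectivity matrix.
#' @param coupling_range,speed_range search intervals.
#' @param n_individuals number of cloud centers.
#' @param cloud_size parameter combinations per cloud.
#' @param n_generations multi-gradient generations.
#' @param learning_rate,shrink_factor see [gd_config()].
#' @param seed experiment seed.
#' @param sim_opts list of extra arguments for [oscillator_network()].
#' @return List with `trajectory`, `best` (named `c(coupling, speed)`),
#'   `best_fitness` and `evaluations_per_generation`.
#' @export
fit_fc <- function(sc, coupling_range = c(0, 0.6), speed_range = c(0.5, 10),
                   n_individuals = 4L, cloud_size = 64L, n_generations = 30L,
                   learning_rate = 0.01, shrink_factor = 0.9, seed = 1L,
                   sim_opts = list()) {
  cfg <- gd_config(learning_rate = learning_rate, mode = "multi",
                   n_individuals = n_individuals, cloud_size = cloud_size,
                   shrink_factor = shrink_factor)
  bounds <- list(low = c(coupling_range[1L], speed_range[1L]),
                 high = c(coupling_range[2L], speed_range[2L]))
  objective <- fcsc_objective(sc, seed, sim_opts)
  spec <- param_spec(coupling = list(low = coupling_range[1L], high = coupling_range[2L]),
                     speed = list(low = speed_range[1L], high = speed_range[2L]))
  traj <- trajectory(config = list(optimizer = "multi_gradient",
                                   n_individuals = n_individuals,
                                   cloud_size = cloud_size), seed = seed)

  set.seed(derive_seed(seed, 0L, 42L))
  half0 <- (bounds$high - bounds$low) / 4
  clouds <- lapply(seq_len(n_individuals), function(i) {
    center <- runif(2L, bounds$low + half0, bounds$high - half0)
    make_cloud(center, half0, cloud_size, bounds = bounds)
  })
  for (g in seq_len(n_generations)) {
    fitness_vectors <- lapply(clouds, function(cl) {
      apply(cl$points, 1L, objective)
    })
    pts <- do.call(rbind, lapply(clouds, `[[`, "points"))
    fs <- unlist(fitness_vectors)
    individuals <- matrix_population(pts, spec, g - 1L)
    records <- lapply(seq_along(fs), function(i) {
      fitness_record(i - 1L, fs[i], fs[i], seed = seed)
    })
    traj <- trajectory_append(traj, individuals, records)
    clouds <- multi_gradient_step(clouds, fitness_vectors, cfg, bounds = bounds)
  }
  best <- trajectory_best(traj)
  list(trajectory = traj,
       best = c(coupling = best$individual$values$coupling,
                speed = best$individual$values$speed),
       best_fitness = best$fitness,
       evaluations_per_generation = n_individuals * cloud_size)
}

#' Deterministic FC-SC objective for a fixed simulation seed
#'
#' @param sc structural connectivity.
#' @param seed seed fixing the oscillator noise realization.
#' @param sim_opts extra [oscillator_network()] arguments.
#' @return `function(point)` mapping `c(coupling, speed)` to the
#'   [fc_sc_fitness()] value.
#' @export
fcsc_objective <- function(sc, seed = 1L, sim_opts = list()) {
  force(sc); force(seed); force(sim_opts)
  function(point) {
    set.seed(derive_seed(seed, 1L, 7L))
    series <- do.call(oscillator_network,
                      c(list(sc = sc, coupling = point[1L], speed = point[2L]),
                        sim_opts))
    fc_sc_fitness(sc, series)
  }
}
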