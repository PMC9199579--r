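#' Adaptive integrate-and-fire toy cell
#'
#' Desk-scale surrogate for a morphologically detailed neuron: a single
#' compartment with leak conductance, spike-triggered adaptation and a
#' hard threshold. Its voltage response to current-clamp stimuli is the
#' target of the trace-fitting pipeline ([fit_cell()]).
#'
#' @param g_l leak conductance (uS).
#' @param e_l leak reversal potential (mV).
#' @param c_m membrane capacitance (nF).
#' @param v_thr spike threshold (mV).
#' @param v_reset post-spike reset (mV).
#' @param b adaptation increment per spike (nA).
#' @param tau_w adaptation time constant (ms).
#' @param spike_height voltage (mV) pasted into the trace at a spike
#'   sample, so threshold-based spike-feature fitness has support.
#' @return A `toy_cell_params` list.
#' @export
toy_cell_params <- function(g_l = 0.02, e_l = -70, c_m = 0.2, v_thr = -50,
                            v_reset = -65, b = 0.04, tau_w = 100,
                            spike_height = 20) {
  stopifnot(g_l > 0, c_m > 0, tau_w > 0, v_thr > v_reset)
  structure(list(g_l = g_l, e_l = e_l, c_m = c_m, v_thr = v_thr,
                 v_reset = v_reset, b = b, tau_w = tau_w,
                 spike_height = spike_height),
            class = "toy_cell_params")
}

#' Current-clamp stimulus
#' @param delay onset (ms), >= 0.
#' @param duration stimulus length (ms), >= 0.
#' @param amplitude injected current (nA).
#' @return A `stimulus_clamp` list.
#' @export
stimulus_clamp <- function(delay, duration, amplitude) {
  stopifnot(delay >= 0, duration >= 0)
  structure(list(delay = delay, duration = duration, amplitude = amplitude),
            class = "stimulus_clamp")
}

#' Simulate the toy cell under a current clamp
#'
#' Deterministic forward-Euler integration of
#' `c_m dV/dt = -g_l (V - e_l) - w + I(t)`, `tau_w dw/dt = -w`, with a
#' spike (trace sample set to `spike_height`, reset, `w <- w + b`) on
#' threshold crossing. An integration step larger than the fastest time
#' constant is refused as numerically unstable.
#'
#' @param params a [toy_cell_params()].
#' @param clamp a [stimulus_clamp()].
#' @param duration simulated time (ms).
#' @param dt integration step (ms).
#' @return A [voltage_trace()] of `duration / dt + 1` samples.
#' @export
toy_cell_trace <- function(params, clamp, duration, dt = 0.1) {
  stopifnot(inherits(params, "toy_cell_params"), inherits(clamp, "stimulus_clamp"),
            duration > 0, dt > 0)
  tau_m <- params$c_m / params$g_l
  if (dt > min(tau_m, params$tau_w)) {
    stop(sprintf("dt = %g ms exceeds the fastest time constant (%g ms); refusing unstable integration",
                 dt, min(tau_m, params$tau_w)), call. = FALSE)
  }
  n_steps <- round(duration / dt)
  samples <- numeric(n_steps + 1L)
  g_l <- params$g_l; e_l <- params$e_l; inv_c <- dt / params$c_m
  v_thr <- params$v_thr; v_reset <- params$v_reset; b <- params$b
  w_decay <- dt / params$tau_w; spike_height <- params$spike_height
  v <- e_l; w <- 0
  samples[1L] <- v
  s_on <- floor(clamp$delay / dt); s_off <- floor((clamp$delay + clamp$duration) / dt)
  amp <- clamp$amplitude
  for (s in seq_len(n_steps)) {
    i_ext <- if (s > s_on && s <= s_off) amp else 0
    v <- v + inv_c * (-g_l * (v - e_l) - w + i_ext)
    w <- w - w_decay * w
    if (v >= v_thr) {
      samples[s + 1L] <- spike_height
      v <- v_reset
      w <- w + b
    } else {
      samples[s + 1L] <- v
    }
  }
  voltage_trace(samples, dt)
}

#' Fit toy-cell parameters to reference traces
#'
#' Parameter-recovery pipeline: reference traces are generated internally
#' from known parameters under each stimulus clamp, then a genetic
#' algorithm searches the free parameters to match them. Two fitness
#' modes: `"mse"` (default) scores each clamp with the negative square
#' loss ([trace_square_loss()], weights all 1); `"features"` scores each
#' clamp with the spike-emphasizing pair ([spike_feature_fitness()]),
#' giving an interleaved fitness vector of length `2 * n_clamps`
#' scalarized with `feature_weights`.
#'
#' @param reference_params the planted [toy_cell_params()].
#' @param clamps list of [stimulus_clamp()]s.
#' @param free named list of `c(low, high)` bounds for the free scalar
#'   parameters (names must be `toy_cell_params` fields).
#' @param n_pop,n_generations GA population size and generation count.
#' @param seed experiment seed.
#' @param duration,dt trace length and integration step (ms).
#' @param fitness_mode `"mse"` or `"features"`.
#' @param sigma spike-selection threshold for the feature mode (mV).
#' @param feature_weights weights for the interleaved (L, S) vector.
#' @param ga arguments passed to [ga_config()].
#' @param n_workers parallel evaluation workers.
#' @return List with `trajectory`, `recovered` (named vector of best-fit
#'   free parameters), `truth` and `best_fitness`.
#' @export
fit_cell <- function(reference_params, clamps, free,
                     n_pop = 100L, n_generations = 200L, seed = 1L,
                     duration = 100, dt = 0.25,
                     fitness_mode = c("mse", "features"), sigma = 0,
                     feature_weights = NULL, ga = list(), n_workers = 1L) {
  fitness_mode <- match.arg(fitness_mode)
  stopifnot(length(clamps) >= 1L, length(free) >= 1L, !is.null(names(free)))
  refs <- lapply(clamps, function(cl) {
    toy_cell_trace(reference_params, cl, duration, dt)
  })
  spec_args <- lapply(free, function(b) list(shape = 1L, low = b[1L], high = b[2L]))
  spec <- do.call(param_spec, spec_args)

  simulate <- function(ind, seed) {
    p <- reference_params
    for (nm in names(free)) p[[nm]] <- ind$values[[nm]]
    class(p) <- "toy_cell_params"
    sims <- lapply(clamps, function(cl) toy_cell_trace(p, cl, duration, dt))
    if (fitness_mode == "mse") {
      vapply(seq_along(clamps), function(k) {
        trace_square_loss(refs[[k]], sims[[k]])
      }, numeric(1))
    } else {
      stimulus_fitness_vector(lapply(seq_along(clamps), function(k) {
        spike_feature_fitness(refs[[k]], sims[[k]], sigma)
      }))
    }
  }
  weights <- if (fitness_mode == "mse") rep(1, length(clamps))
             else if (!is.null(feature_weights)) feature_weights
             else rep(c(-1, -1), length(clamps))
  config <- experiment_config(
    optimizee = list(spec = spec, simulate = simulate),
    optimizer = do.call(optimizer_ga, ga),
    n_pop = n_pop, n_generations = n_generations,
    weights = weights, n_workers = n_workers, seed = seed)
  traj <- run_experiment(config)
  best <- trajectory_best(traj)
  recovered <- vapply(names(free), function(nm) best$individual$values[[nm]], numeric(1))
  truth <- vapply(names(free), function(nm) reference_params[[nm]], numeric(1))
  list(trajectory = traj, recovered = recovered, truth = truth,
       best_fitness = best$fitness)
}
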