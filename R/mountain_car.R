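#' Mountain-car environment
#'
#' Standard underpowered-car-on-a-hill control problem: state is
#' `(position, velocity)` with position in [-1.2, 0.6] and velocity in
#' [-0.07, 0.07]; actions are accelerate left (0), do nothing (1),
#' accelerate right (2). Per step
#' `velocity <- velocity + 0.001 * (action - 1) - 0.0025 * cos(3 * position)`
#' (clamped), then `position <- position + velocity` (clamped); the
#' episode is done when the position reaches the 0.5 goal. `mc_reset`
#' draws the start uniformly in the valley `[-0.6, -0.4]` with zero
#' velocity.
#'
#' @return `mc_reset`: list `(position, velocity)`;
#'   `mc_step`: list `(state, done)`.
#' @export
mc_reset <- function() {
  list(position = runif(1, -0.6, -0.4), velocity = 0)
}

#' @rdname mc_reset
#' @param state list with `position` and `velocity`.
#' @param action integer in `{0, 1, 2}` (left, none, right).
#' @export
mc_step <- function(state, action) {
  stopifnot(action %in% c(0L, 1L, 2L))
  v <- state$velocity + 0.001 * (action - 1) - 0.0025 * cos(3 * state$position)
  v <- min(max(v, -0.07), 0.07)
  p <- min(max(state$position + v, -1.2), 0.6)
  if (p <= -1.2 && v < 0) v <- 0
  list(state = list(position = p, velocity = v), done = p >= 0.5)
}

#' Run one mountain-car episode under a spiking policy network
#'
#' Closed-loop control: per environment step, the car's position and
#' velocity are discretized ([bin_index()], 30 bins each) to pick the two
#' active input neurons, the 60-5-3 policy network is simulated for
#' `interval_ms` with those inputs under calibrated DC drive, and the
#' action is decoded from the output spike counts by [winner_take_all()]
#' (default action: do nothing). Membrane state persists across steps.
#'
#' @param weights the 315 policy weights (or a prebuilt
#'   [build_mc_policy()] network).
#' @param max_steps episode cap (110 during training evaluations, 200 for
#'   evaluation episodes).
#' @param start optional fixed start state; default [mc_reset()].
#' @param interval_ms network simulation time per environment step (ms).
#' @param dt integration step (ms).
#' @param velocity_range encoder range for the velocity bins. The default
#'   is a wide range that collapses the reachable velocities
#'   (never beyond 0.07 in magnitude) onto the two central bins - an
#'   effective sign-of-velocity code that favors robust momentum-following
#'   policies; set to `c(-0.07, 0.07)` for a full-resolution encoder.
#' @param engine `"cpp"` (default) runs the whole closed loop in compiled
#'   code; `"r"` composes [bin_index()], [simulate_network()] and
#'   [winner_take_all()] step by step. The two produce identical episodes.
#' @return List with `positions` (per-step trace), `steps_to_goal`
#'   (`NA` if the goal was not reached) and `actions`.
#' @export
run_mc_episode <- function(weights, max_steps = 110L, start = NULL,
                           interval_ms = 20, dt = 0.1,
                           velocity_range = c(-0.7, 0.7),
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  net <- if (inherits(weights, "network_spec")) weights else build_mc_policy(weights)
  dc <- attr(net, "input_dc")
  out <- net$populations$output
  state <- if (is.null(start)) mc_reset() else start
  if (engine == "cpp") {
    p <- net$params
    res <- mc_episode_cpp(net$synapses$weight, state$position, state$velocity,
                          as.integer(max_steps), interval_ms, dt, dc,
                          p$tau_m, p$v_rest, p$v_reset, p$v_thr, p$t_ref,
                          p$r_m, velocity_range[1L], velocity_range[2L])
    return(list(positions = res$positions,
                steps_to_goal = if (is.na(res$steps_to_goal)) NA_integer_
                                else as.integer(res$steps_to_goal),
                actions = res$actions))
  }
  sim_state <- NULL
  positions <- numeric(0)
  actions <- integer(0)
  steps_to_goal <- NA_integer_
  for (s in seq_len(max_steps)) {
    p_bin <- bin_index(state$position, -1.2, 0.6, 30L)
    v_bin <- bin_index(state$velocity, velocity_range[1L], velocity_range[2L], 30L)
    drv <- data.frame(neuron = c(p_bin + 1L, 30L + v_bin + 1L),
                      start = 0, end = interval_ms, amplitude = dc)
    rec <- simulate_network(net, drv, interval_ms, dt, state = sim_state)
    sim_state <- rec$state
    action <- winner_take_all(rec$counts[out], default = 2L) - 1L
    stepped <- mc_step(state, action)
    state <- stepped$state
    positions <- c(positions, state$position)
    actions <- c(actions, action)
    if (stepped$done) { steps_to_goal <- s; break }
  }
  list(positions = positions, steps_to_goal = steps_to_goal, actions = actions)
}

#' Evolve the mountain-car policy with a genetic algorithm
#'
#' Outer loop over the 315 policy weights (bounded to [-20, 20]): each
#' individual's fitness is the maximum position reached in one training
#' episode of at most 110 steps ([mc_fitness()]). The run executes all
#' generations by default: continued selection after the goal is first
#' reached is what hardens the champion across start positions; set
#' `target_fitness = 0.5` to stop at the first solving individual.
#'
#' @param n_pop population size.
#' @param n_generations generation cap.
#' @param seed experiment seed.
#' @param n_workers parallel evaluation workers.
#' @param max_steps training episode cap.
#' @param ga arguments passed to [ga_config()].
#' @param target_fitness optional early-stop fitness.
#' @param velocity_range encoder range (see [run_mc_episode()]).
#' @param verbose print progress.
#' @return The run [trajectory()].
#' @export
evolve_mc_policy <- function(n_pop = 32L, n_generations = 400L, seed = 1L,
                             n_workers = 1L, max_steps = 110L,
                             ga = list(), target_fitness = NULL,
                             velocity_range = c(-0.7, 0.7), verbose = FALSE) {
  optimizee <- mc_optimizee(max_steps = max_steps,
                            velocity_range = velocity_range)
  config <- experiment_config(
    optimizee = optimizee,
    optimizer = do.call(optimizer_ga, ga),
    n_pop = n_pop, n_generations = n_generations,
    weights = 1, n_workers = n_workers, seed = seed,
    target_fitness = target_fitness)
  run_experiment(config, verbose = verbose)
}

#' @rdname evolve_mc_policy
#' @param common_start_seed when non-`NULL`, all individuals of a
#'   generation face the same (generation-specific) random episode start,
#'   so within-generation fitness comparisons are fair; starts still vary
#'   across generations. `NULL` gives every evaluation its own start.
#' @export
mc_optimizee <- function(max_steps = 110L, velocity_range = c(-0.7, 0.7),
                         common_start_seed = NULL) {
  list(
    spec = param_spec(w = list(shape = 315L, low = -20, high = 20)),
    simulate = function(ind, seed) {
      if (!is.null(common_start_seed)) {
        set.seed(derive_seed(common_start_seed, ind$generation, 77L))
      }
      ep <- run_mc_episode(ind$values$w, max_steps = max_steps,
                           velocity_range = velocity_range)
      mc_fitness(ep$positions)
    })
}

#' Nominate the champion policy from one or more evolution runs
#'
#' Training fitness is the maximum position of a single random episode, so
#' the highest-fitness individual of a run is partly a draw of episode
#' luck. The championing rule therefore shortlists the `k` highest-fitness
#' individuals of each trajectory and validates every candidate on a small
#' set of fresh episodes; the candidate with the lowest validated mean
#' steps-to-goal is the run's champion. Validation episodes are disjoint
#' (by seed) from any later evaluation.
#'
#' @param trajectories a [trajectory()] or list of trajectories.
#' @param k candidates shortlisted per trajectory.
#' @param n_val validation episodes per candidate.
#' @param max_steps validation episode cap.
#' @param seed seed for the validation episode starts.
#' @param velocity_range encoder range (see [run_mc_episode()]).
#' @return List with `weights` (the champion's 315 policy weights),
#'   `fitness` (its training fitness) and `val_mean_steps`.
#' @export
mc_select_champion <- function(trajectories, k = 5L, n_val = 10L,
                               max_steps = 200L, seed = 1L,
                               velocity_range = c(-0.7, 0.7)) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  candidates <- list()
  for (traj in trajectories) {
    inds <- list(); fs <- numeric(0)
    for (gen in traj$generations) {
      inds <- c(inds, gen$individuals)
      fs <- c(fs, vapply(gen$records, `[[`, numeric(1), "scalar_fitness"))
    }
    top <- order(fs, decreasing = TRUE)[seq_len(min(k, length(fs)))]
    candidates <- c(candidates, lapply(top, function(i) {
      list(weights = inds[[i]]$values$w, fitness = fs[i])
    }))
  }
  vals <- vapply(seq_along(candidates), function(i) {
    mc_evaluate(candidates[[i]]$weights, n_episodes = n_val,
                max_steps = max_steps,
                seed = derive_seed(seed, 333L, i),
                velocity_range = velocity_range)$mean_steps
  }, numeric(1))
  best <- which.min(vals)
  list(weights = candidates[[best]]$weights,
       fitness = candidates[[best]]$fitness,
       val_mean_steps = vals[best])
}

#' Evaluate a fixed policy over many episodes
#'
#' Runs `n_episodes` randomly initialized episodes (cap `max_steps`) and
#' reports the mean steps-to-goal, counting episodes that never reach the
#' goal as `max_steps`.
#'
#' @param weights the 315 policy weights.
#' @param n_episodes number of evaluation episodes.
#' @param max_steps per-episode cap.
#' @param seed RNG seed for the episode starts.
#' @param velocity_range encoder range (see [run_mc_episode()]).
#' @return List with `mean_steps`, `success_rate` and the per-episode
#'   `steps` vector.
#' @export
mc_evaluate <- function(weights, n_episodes = 100L, max_steps = 200L, seed = 1L,
                        velocity_range = c(-0.7, 0.7)) {
  net <- build_mc_policy(weights)
  set.seed(seed)
  eps <- lapply(seq_len(n_episodes), function(i) {
    ep <- run_mc_episode(net, max_steps = max_steps,
                         velocity_range = velocity_range)
    ep$steps_to_goal
  })
  reached <- !vapply(eps, is.na, logical(1))
  steps <- vapply(eps, function(s) if (is.na(s)) max_steps else as.numeric(s), numeric(1))
  list(mean_steps = mean(steps), success_rate = mean(reached), steps = steps)
}
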