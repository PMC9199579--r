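#' Leaky integrate-and-fire neuron parameters
#'
#' Current-based point neuron with delta synapses: the membrane potential
#' decays toward `v_rest` with time constant `tau_m`, presynaptic spikes
#' add their synaptic weight (mV) directly after their delay, external
#' drive enters as `r_m * I`, and crossing `v_thr` emits a spike followed
#' by a reset to `v_reset` and an absolute refractory period `t_ref`.
#'
#' @param tau_m membrane time constant (ms).
#' @param v_rest resting potential (mV); also the reset value by default.
#' @param v_reset post-spike reset potential (mV).
#' @param v_thr spike threshold (mV), must exceed `v_reset`.
#' @param t_ref absolute refractory period (ms).
#' @param r_m membrane resistance (MOhm) scaling external drive.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(tau_m = 10, v_rest = -70, v_reset = -70,
                       v_thr = -55, t_ref = 2, r_m = 1) {
  stopifnot(tau_m > 0, t_ref >= 0, r_m > 0)
  if (v_thr <= v_reset) stop("threshold must exceed the reset potential", call. = FALSE)
  structure(list(tau_m = tau_m, v_rest = v_rest, v_reset = v_reset,
                 v_thr = v_thr, t_ref = t_ref, r_m = r_m),
            class = "lif_params")
}

#' Closed-form firing rate of a LIF neuron under constant drive
#'
#' For steady potential `v_inf = v_rest + r_m * I` above threshold, the
#' interspike interval is `t_ref + tau_m * log((v_inf - v_reset) /
#' (v_inf - v_thr))` and the rate its reciprocal (in Hz); 0 for
#' subthreshold drive. Used as the independent oracle for the simulator
#' and to calibrate DC amplitudes for a desired rate
#' ([lif_dc_for_rate()]).
#'
#' @param amplitude constant drive (current units).
#' @param params a [lif_params()].
#' @return Firing rate in Hz.
#' @export
lif_rate_closed_form <- function(amplitude, params) {
  v_inf <- params$v_rest + params$r_m * amplitude
  if (v_inf <= params$v_thr) return(0)
  isi <- params$t_ref +
    params$tau_m * log((v_inf - params$v_reset) / (v_inf - params$v_thr))
  1000 / isi
}

#' @rdname lif_rate_closed_form
#' @param rate_hz target firing rate (Hz); must be below `1000 / t_ref`.
#' @export
lif_dc_for_rate <- function(rate_hz, params) {
  stopifnot(rate_hz > 0, rate_hz < 1000 / params$t_ref)
  t_int <- 1000 / rate_hz - params$t_ref
  gap <- params$v_thr - params$v_reset
  # solve v_inf from isi: (v_inf - v_reset)/(v_inf - v_thr) = exp(t/tau)
  r <- exp(t_int / params$tau_m)
  v_inf <- (r * params$v_thr - params$v_reset) / (r - 1)
  (v_inf - params$v_rest) / params$r_m
}

#' Define a spiking network for the LIF simulator
#'
#' A network is a neuron count, shared LIF parameters, a synapse table
#' (`pre`, `post`, `weight` in mV, `delay` in integer steps >= 1), labeled
#' populations (index vectors), and a per-neuron `is_source` flag marking
#' rate-coded Poisson source neurons (their drive amplitude is read as a
#' firing rate in Hz instead of a current).
#'
#' @param n_neurons number of neurons.
#' @param synapses data frame with columns `pre`, `post`, `weight`,
#'   `delay`.
#' @param populations named list of neuron index vectors.
#' @param params a [lif_params()].
#' @param is_source logical vector of length `n_neurons`.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_neurons, synapses, populations = list(),
                         params = lif_params(), is_source = NULL) {
  n_neurons <- as.integer(n_neurons)
  stopifnot(n_neurons >= 1L, inherits(params, "lif_params"))
  synapses <- as.data.frame(synapses)
  need <- c("pre", "post", "weight", "delay")
  if (!all(need %in% names(synapses))) {
    stop("synapse table needs columns pre, post, weight, delay", call. = FALSE)
  }
  synapses$pre <- as.integer(synapses$pre)
  synapses$post <- as.integer(synapses$post)
  synapses$delay <- as.integer(synapses$delay)
  if (nrow(synapses) > 0L) {
    stopifnot(all(synapses$pre >= 1L), all(synapses$pre <= n_neurons),
              all(synapses$post >= 1L), all(synapses$post <= n_neurons))
    if (any(synapses$delay < 1L)) stop("no synapse may have delay < 1 step", call. = FALSE)
  }
  if (is.null(is_source)) is_source <- rep(FALSE, n_neurons)
  stopifnot(length(is_source) == n_neurons)
  for (p in populations) stopifnot(all(p >= 1L), all(p <= n_neurons))
  structure(list(n_neurons = n_neurons, synapses = synapses,
                 populations = populations, params = params,
                 is_source = as.logical(is_source)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d neurons, %d synapses\n",
              x$n_neurons, nrow(x$synapses)))
  for (nm in names(x$populations)) {
    cat(sprintf("  population %s: %d neurons\n", nm, length(x$populations[[nm]])))
  }
  invisible(x)
}

#' Write / read a network's synapse table as a CSV edge list
#'
#' Columns `pre, post, weight, delay`, compatible with the external
#' CSV-exchange optimizee coupling.
#'
#' @param net a [network_spec()] (for writing).
#' @param path CSV file path.
#' @return `write_network_csv`: `path` invisibly; `read_network_csv`: the
#'   synapse data frame.
#' @export
write_network_csv <- function(net, path) {
  write.csv(net$synapses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(path) {
  df <- read.csv(path)
  need <- c("pre", "post", "weight", "delay")
  if (!all(need %in% names(df))) {
    stop("edge list needs columns pre, post, weight, delay", call. = FALSE)
  }
  df[need]
}

#' Simulate a LIF network
#'
#' Forward-Euler integration with delta-current synapses, delay queues and
#' optional Poisson background impulses. External drive is
#' piecewise-constant per neuron (a data frame of intervals); for source
#' neurons the amplitude is read as a Poisson rate in Hz. Randomness (only
#' background noise and source spiking) follows the R RNG, so runs are
#' deterministic under `set.seed()`. Passing the `state` of a previous
#' call continues the simulation seamlessly (membrane potentials,
#' refractory counters and in-flight delayed currents are all carried).
#'
#' @param net a [network_spec()].
#' @param drive `NULL` or data frame with columns `neuron`, `start`,
#'   `end` (ms), `amplitude`.
#' @param duration simulated time (ms); must be a multiple of `dt`.
#' @param dt integration step (ms).
#' @param bg_rate Poisson background impulse rate per neuron (Hz).
#' @param bg_weight potential kick per background impulse (mV).
#' @param state `NULL` or the `state` element of a previous result.
#' @param record_times also record per-neuron spike times (ms).
#' @return A `spike_record`: list with `counts` (per-neuron spike counts),
#'   optional `times`, `duration`, `dt`, and `state` for continuation.
#' @export
simulate_network <- function(net, drive = NULL, duration, dt = 0.1,
                             bg_rate = 0, bg_weight = 0.5, state = NULL,
                             record_times = FALSE) {
  stopifnot(inherits(net, "network_spec"), duration > 0, dt > 0)
  if (abs(duration / dt - round(duration / dt)) > 1e-9) {
    stop("dt must divide duration", call. = FALSE)
  }
  if (is.null(drive)) {
    drive <- data.frame(neuron = integer(0), start = numeric(0),
                        end = numeric(0), amplitude = numeric(0))
  }
  p <- net$params
  res <- lif_run_cpp(net$n_neurons, p$tau_m, p$v_rest, p$v_reset, p$v_thr,
                     p$t_ref, p$r_m, net$is_source,
                     net$synapses$pre, net$synapses$post,
                     net$synapses$weight, net$synapses$delay,
                     as.integer(drive$neuron), as.numeric(drive$start),
                     as.numeric(drive$end), as.numeric(drive$amplitude),
                     duration, dt, bg_rate, bg_weight, state, record_times)
  structure(list(counts = res$counts,
                 times = if (record_times) res$times else NULL,
                 duration = duration, dt = dt, state = res$state),
            class = "spike_record")
}
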