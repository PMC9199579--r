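#' Rate-code pixel intensities
#'
#' Affine map of 8-bit pixel intensities to input firing rates:
#' `rate = 1 + 99 * p / 255`, so 0 maps to 1 Hz and 255 to 100 Hz.
#'
#' @param pixels numeric vector with values in [0, 255].
#' @return Firing rates in Hz.
#' @export
encode_pixels_to_rates <- function(pixels) {
  if (any(pixels < 0 | pixels > 255)) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  1 + 99 * pixels / 255
}

#' Discretize a continuous value into one of n bins
#'
#' Bin width `w = (high - low) / n`; the index is
#' `floor((value - low) / w)`, clamped to `[0, n - 1]` so `value = high`
#' falls in the last bin.
#'
#' @param value numeric value(s) to bin.
#' @param low,high interval bounds, `low < high`.
#' @param n number of bins, >= 1.
#' @return Integer bin index (0-based) in `[0, n - 1]`.
#' @export
bin_index <- function(value, low, high, n) {
  if (low >= high) stop("low must be < high", call. = FALSE)
  stopifnot(n >= 1L)
  w <- (high - low) / n
  pmin(pmax(as.integer(floor((value - low) / w)), 0L), n - 1L)
}

#' Winner-take-all decoding of output spike counts
#'
#' The output unit with the highest spike count determines the decoded
#' index. Ties are broken toward the lowest index; an all-zero count
#' vector returns the configured default.
#'
#' @param spike_counts nonempty numeric vector of per-unit spike counts.
#' @param default 1-based index returned when no unit spiked.
#' @return 1-based index of the winning unit.
#' @export
winner_take_all <- function(spike_counts, default = 1L) {
  stopifnot(length(spike_counts) >= 1L)
  if (all(spike_counts == 0)) return(as.integer(default))
  which.max(spike_counts)
}

.sample_targets <- function(pool, k) pool[sample.int(length(pool), k)]

#' Build the spiking reservoir classifier network
#'
#' Three-layer liquid-state-machine architecture: a pixel-driven input
#' layer (768 rate-coded source neurons at full scale, one per pixel), a
#' recurrent reservoir of 1600 excitatory and 400 inhibitory neurons with
#' outdegrees capped at 6% (excitatory) and 8% (inhibitory) of the
#' reservoir, and 3 output clusters of 12 neurons (10 excitatory, 2
#' inhibitory) - recurrently connected within a cluster, never across
#' clusters. Each output neuron draws exactly 800 reservoir sources, giving
#' 28 800 reservoir-to-output synapses at full scale. Weights are sampled
#' from N(70, 50) for excitatory and N(-90, 50) for inhibitory sources.
#' `scale` shrinks every population proportionally while preserving the
#' ratios; the readout synapses (reservoir to output) are the trainable
#' parameters ([train_reservoir()]).
#'
#' @param scale population scale factor in (0, 1].
#' @param n_classes number of output clusters.
#' @param params a [lif_params()].
#' @param efficacy conversion factor (mV of postsynaptic kick per sampled
#'   weight unit) for the input and recurrent synapses. The sampled weight
#'   distributions are in the units of a conductance-based simulator; with
#'   delta-current synapses a 70-unit weight must not depolarize by 70 mV,
#'   so the builder converts units to millivolts here.
#' @param readout_efficacy conversion factor for the reservoir-to-output
#'   (readout) synapses; smaller, because each output neuron pools 800
#'   sources at full scale and must stay in its dynamic range.
#' @return A [network_spec()] with populations `input`, `reservoir`,
#'   `output` and `output_cluster_<k>`, plus attributes `readout`
#'   (row indices of the readout synapses in the synapse table) and
#'   `n_pixels`.
#' @export
build_reservoir <- function(scale = 1, n_classes = 3L, params = lif_params(),
                            efficacy = 0.1, readout_efficacy = 0.01) {
  stopifnot(scale > 0, scale <= 1, n_classes >= 2L)
  n_in <- round(768 * scale)
  n_exc <- round(1600 * scale)
  n_inh <- round(400 * scale)
  n_out_exc <- round(10 * scale)
  n_out_inh <- round(2 * scale)
  if (n_in < 1 || n_exc < 1 || n_inh < 1) {
    stop("scale too small: empty population", call. = FALSE)
  }
  if (n_out_exc < 1) stop("scale produces an empty output cluster", call. = FALSE)
  n_clu <- n_out_exc + n_out_inh
  n_res <- n_exc + n_inh
  n_readout_src <- max(1L, round(800 * scale))

  input <- seq_len(n_in)
  reservoir <- n_in + seq_len(n_res)
  res_exc <- reservoir[seq_len(n_exc)]
  res_inh <- reservoir[n_exc + seq_len(n_inh)]
  out_start <- n_in + n_res
  outputs <- lapply(seq_len(n_classes), function(k) {
    out_start + (k - 1L) * n_clu + seq_len(n_clu)
  })
  n_total <- out_start + n_classes * n_clu

  w_exc <- function(k) rnorm(k, 70, 50) * efficacy
  w_inh <- function(k) rnorm(k, -90, 50) * efficacy
  edges <- list()
  add <- function(pre, post, w) {
    edges[[length(edges) + 1L]] <<- data.frame(pre = pre, post = post,
                                               weight = w, delay = 1L)
  }
  # input -> reservoir: excitatory, 6% outdegree like reservoir excitatory
  k_in <- max(1L, round(0.06 * n_res))
  for (i in input) add(rep(i, k_in), .sample_targets(reservoir, k_in), w_exc(k_in))
  # recurrent reservoir with capped outdegree
  k_exc <- max(1L, round(0.06 * n_res))
  k_inh <- max(1L, round(0.08 * n_res))
  for (i in res_exc) add(rep(i, k_exc), .sample_targets(reservoir, k_exc), w_exc(k_exc))
  for (i in res_inh) add(rep(i, k_inh), .sample_targets(reservoir, k_inh), w_inh(k_inh))
  # reservoir -> output: the readout, n_readout_src sources per output neuron
  readout_first <- sum(vapply(edges, nrow, integer(1))) + 1L
  for (cluster in outputs) {
    for (o in cluster) {
      src <- .sample_targets(reservoir, n_readout_src)
      w <- ifelse(src %in% res_exc, rnorm(length(src), 70, 50),
                  rnorm(length(src), -90, 50)) * readout_efficacy
      add(src, rep(o, length(src)), w)
    }
  }
  readout_last <- sum(vapply(edges, nrow, integer(1)))
  # recurrent within each output cluster (no self-loops), never across
  for (cluster in outputs) {
    exc_part <- cluster[seq_len(n_out_exc)]
    for (o in cluster) {
      tgt <- setdiff(cluster, o)
      if (length(tgt) > 0L) {
        w <- if (o %in% exc_part) w_exc(length(tgt)) else w_inh(length(tgt))
        add(rep(o, length(tgt)), tgt, w)
      }
    }
  }

  synapses <- do.call(rbind, edges)
  populations <- c(list(input = input, reservoir = reservoir),
                   setNames(outputs, paste0("output_cluster_", seq_len(n_classes))),
                   list(output = unlist(outputs)))
  is_source <- rep(FALSE, n_total)
  is_source[input] <- TRUE
  net <- network_spec(n_total, synapses, populations, params, is_source)
  attr(net, "readout") <- seq.int(readout_first, readout_last)
  attr(net, "n_pixels") <- n_in
  attr(net, "res_exc") <- res_exc
  net
}

#' Build the 12-10-4 foraging-agent brain network
#'
#' Fixed topology with 250 synapses: 11 sensory input neurons all-to-all
#' to 10 hidden neurons (110), the heartbeat neuron (input 12) to all
#' hidden neurons (10), hidden recurrent all-to-all without self-loops
#' (90), and hidden all-to-all to 4 output neurons (40). The synapse order
#' is deterministic (blocks in that order, row-major by presynaptic then
#' postsynaptic index), so flat 250-vectors of weights and delays map
#' stably onto the table.
#'
#' @param weights numeric vector of exactly 250 synaptic weights (mV).
#' @param delays integer vector of exactly 250 delays (steps >= 1).
#' @param params a [lif_params()].
#' @return A [network_spec()] with populations `input`, `heartbeat`,
#'   `hidden`, `output`.
#' @export
build_ant_brain <- function(weights, delays = rep(1L, 250L),
                            params = lif_params()) {
  if (length(weights) != 250L || length(delays) != 250L) {
    stop(sprintf("expected 250 weights and 250 delays, got %d and %d",
                 length(weights), length(delays)), call. = FALSE)
  }
  input <- 1:11; heartbeat <- 12L; hidden <- 12L + 1:10; output <- 22L + 1:4
  pre <- integer(0); post <- integer(0)
  for (i in input) { pre <- c(pre, rep(i, 10L)); post <- c(post, hidden) }        # 110
  pre <- c(pre, rep(heartbeat, 10L)); post <- c(post, hidden)                     # 10
  for (i in hidden) { tgt <- setdiff(hidden, i)
    pre <- c(pre, rep(i, 9L)); post <- c(post, tgt) }                             # 90
  for (i in hidden) { pre <- c(pre, rep(i, 4L)); post <- c(post, output) }        # 40
  synapses <- data.frame(pre = pre, post = post,
                         weight = as.numeric(weights),
                         delay = as.integer(delays))
  network_spec(26L, synapses,
               list(input = input, heartbeat = heartbeat,
                    hidden = hidden, output = output),
               params)
}

#' Build the 60-5-3 mountain-car policy network
#'
#' Feed-forward network: 60 input neurons (30 position bins, then 30
#' velocity bins) all-to-all to 5 intermediate neurons (300 synapses),
#' all-to-all to 3 output neurons - one per action (15 synapses); 315
#' weights in total, ordered input-to-hidden then hidden-to-output,
#' row-major by presynaptic index. The active input neuron of each
#' variable is driven by a DC amplitude calibrated through the closed-form
#' LIF f-I curve to fire near the 500 Hz refractory ceiling.
#'
#' @param weights numeric vector of exactly 315 synaptic weights (mV).
#' @param params a [lif_params()].
#' @return A [network_spec()] with populations `input`, `hidden`,
#'   `output` and attribute `input_dc` (the calibrated drive amplitude).
#' @export
build_mc_policy <- function(weights, params = lif_params()) {
  if (length(weights) != 315L) {
    stop(sprintf("expected 315 weights, got %d", length(weights)), call. = FALSE)
  }
  input <- 1:60; hidden <- 60L + 1:5; output <- 65L + 1:3
  pre <- integer(0); post <- integer(0)
  for (i in input) { pre <- c(pre, rep(i, 5L)); post <- c(post, hidden) }
  for (i in hidden) { pre <- c(pre, rep(i, 3L)); post <- c(post, output) }
  synapses <- data.frame(pre = pre, post = post,
                         weight = as.numeric(weights), delay = 1L)
  net <- network_spec(68L, synapses,
                      list(input = input, hidden = hidden, output = output),
                      params)
  attr(net, "input_dc") <- lif_dc_for_rate(495, params)
  net
}

#' Digit presentation protocol
#'
#' Timing and background of a classification run: a warmup with background
#' noise only so the network decays to rest, then per image a presentation
#' phase (pixels rate-coded into the input sources) followed by a cooling
#' phase with no input.
#'
#' @param warmup_ms,present_ms,cool_ms phase durations (ms).
#' @param bg_rate background Poisson impulse rate per neuron (Hz).
#' @param bg_weight background impulse amplitude (mV).
#' @return A `digit_protocol` list.
#' @export
digit_protocol <- function(warmup_ms = 100, present_ms = 500, cool_ms = 200,
                           bg_rate = 5, bg_weight = 10) {
  structure(list(warmup_ms = warmup_ms, present_ms = present_ms,
                 cool_ms = cool_ms, bg_rate = bg_rate, bg_weight = bg_weight),
            class = "digit_protocol")
}

#' Present a batch of images to a reservoir network
#'
#' Runs the full protocol: warmup (background only), then per image the
#' pixel rates drive the input sources for the presentation phase and the
#' network cools down with no input. Membrane state carries across the
#' whole batch. Returns the per-image mean firing rate (Hz) of each output
#' cluster during the presentation window; the softmax of these rates is
#' the classifier output. Images with more pixels than the input layer are
#' truncated to the layer size.
#'
#' @param net a [build_reservoir()] network.
#' @param images matrix, one image per row, pixel values in [0, 255].
#' @param protocol a [digit_protocol()].
#' @param dt integration step (ms).
#' @return `n_images x n_clusters` matrix of output-cluster rates, with
#'   attribute `total_time_ms`.
#' @export
run_digit_protocol <- function(net, images, protocol = digit_protocol(),
                               dt = 0.1) {
  images <- as.matrix(images)
  n_px <- attr(net, "n_pixels")
  if (ncol(images) > n_px) images <- images[, seq_len(n_px), drop = FALSE]
  if (ncol(images) != n_px) {
    stop(sprintf("images have %d pixels but the input layer expects %d",
                 ncol(images), n_px), call. = FALSE)
  }
  clusters <- net$populations[grep("^output_cluster_", names(net$populations))]
  input <- net$populations$input

  rec <- simulate_network(net, NULL, protocol$warmup_ms, dt,
                          bg_rate = protocol$bg_rate,
                          bg_weight = protocol$bg_weight)
  state <- rec$state
  rates <- matrix(0, nrow(images), length(clusters))
  for (im in seq_len(nrow(images))) {
    drv <- data.frame(neuron = input, start = 0,
                      end = protocol$present_ms,
                      amplitude = encode_pixels_to_rates(images[im, ]))
    rec <- simulate_network(net, drv, protocol$present_ms, dt,
                            bg_rate = protocol$bg_rate,
                            bg_weight = protocol$bg_weight, state = state)
    state <- rec$state
    for (k in seq_along(clusters)) {
      cl <- clusters[[k]]
      rates[im, k] <- sum(rec$counts[cl]) / length(cl) / (protocol$present_ms / 1000)
    }
    rec <- simulate_network(net, NULL, protocol$cool_ms, dt,
                            bg_rate = protocol$bg_rate,
                            bg_weight = protocol$bg_weight, state = state)
    state <- rec$state
  }
  attr(rates, "total_time_ms") <- protocol$warmup_ms +
    nrow(images) * (protocol$present_ms + protocol$cool_ms)
  rates
}
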