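#' Softmax of a numeric vector
#'
#' Numerically safe (shift-invariant: the maximum is subtracted before
#' exponentiation), so arbitrarily large firing rates do not overflow.
#'
#' @param x finite numeric vector.
#' @return Probability vector of the same length (components in [0, 1],
#'   summing to 1).
#' @export
softmax <- function(x) {
  if (length(x) == 0L) stop("softmax of an empty vector", call. = FALSE)
  if (!all(is.finite(x))) stop("softmax requires finite inputs", call. = FALSE)
  e <- exp(x - max(x))
  e / sum(e)
}

#' Classification fitness from one-hot label and prediction
#'
#' Mean-squared-error loss `L = mean((y - yhat)^2)` turned into a
#' maximization fitness `f = 1 - L`; the maximum of 1 is attained exactly
#' when the prediction equals the label.
#'
#' @param label_onehot one-hot encoded label vector.
#' @param prediction model output vector (e.g. a [softmax()] vector).
#' @return Scalar fitness `1 - L`.
#' @export
mse_fitness <- function(label_onehot, prediction) {
  if (length(label_onehot) != length(prediction)) {
    stop("label and prediction lengths differ", call. = FALSE)
  }
  1 - mean((label_onehot - prediction)^2)
}

#' A sampled membrane-voltage trace
#' @param samples numeric voltage samples (mV), length >= 2.
#' @param dt sampling interval (ms), > 0.
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(samples, dt) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("a voltage trace needs >= 2 samples", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  structure(list(samples = samples, dt = dt), class = "voltage_trace")
}

.check_aligned <- function(ref, sim) {
  stopifnot(inherits(ref, "voltage_trace"), inherits(sim, "voltage_trace"))
  if (length(ref$samples) != length(sim$samples) || ref$dt != sim$dt) {
    stop("reference and simulated traces must share length and dt", call. = FALSE)
  }
}

#' Negative square loss between two voltage traces
#'
#' `-(1/T^2) * sum_t (U_ref - U_sim)^2` over the T+1 aligned samples, i.e.
#' the square loss negated for the maximization convention. The `1/T^2`
#' prefactor is the default; `normalization = "mean"` switches to the
#' conventional `1/T` temporal mean.
#'
#' @param ref,sim aligned [voltage_trace()]s (equal length and dt).
#' @param normalization `"t_squared"` (default) or `"mean"`.
#' @return Nonpositive scalar fitness; 0 iff the traces are identical.
#' @export
trace_square_loss <- function(ref, sim, normalization = c("t_squared", "mean")) {
  .check_aligned(ref, sim)
  normalization <- match.arg(normalization)
  t_steps <- length(ref$samples) - 1L
  ss <- sum((ref$samples - sim$samples)^2)
  -ss / if (normalization == "t_squared") t_steps^2 else t_steps
}

#' Spike-emphasizing feature fitness for a trace pair
#'
#' Two features computed from aligned traces: `L`, the absolute difference
#' of the temporal means, and `S`, the temporal average of
#' `U_ref - U_sim` restricted to samples where the reference exceeds the
#' spike-selection threshold `sigma` (0 by convention when no sample
#' does). `L` is nonnegative; `S` carries the sign of the mismatch within
#' the spiking region.
#'
#' @param ref,sim aligned [voltage_trace()]s.
#' @param sigma spike-selection threshold (mV).
#' @return Numeric `c(L, S)`.
#' @export
spike_feature_fitness <- function(ref, sim, sigma) {
  .check_aligned(ref, sim)
  l <- abs(mean(ref$samples) - mean(sim$samples))
  sel <- ref$samples > sigma
  s <- if (any(sel)) mean(ref$samples[sel] - sim$samples[sel]) else 0
  c(L = unname(l), S = unname(s))
}

#' Interleave per-stimulus (L, S) pairs into one fitness vector
#'
#' Multi-stimulus trace fitting produces one `(L, S)` pair per stimulus;
#' the overall fitness is the interleaved vector
#' `(L_1, S_1, L_2, S_2, ...)`, scalarized downstream by
#' [weighted_fitness()] with the experiment's weight tuple.
#'
#' @param per_stimulus list of length-2 numeric vectors `(L, S)`.
#' @return Numeric vector of length `2 * n_stimuli`.
#' @export
stimulus_fitness_vector <- function(per_stimulus) {
  stopifnot(length(per_stimulus) >= 1L)
  as.numeric(unlist(lapply(per_stimulus, function(p) p[1:2])))
}

#' Per-event reward/cost constants for the foraging-colony fitness
#'
#' Signed contributions per logged event: costs (negative) for rotation,
#' pheromone dropping, movement and resting; rewards (positive) for
#' touching food and returning to the nest with it. Movement is the most
#' expensive action to discourage aimless wandering; the large nest-return
#' reward makes completing a delivery dominate everything else.
#'
#' @param rotation,pheromone_drop,movement,resting,nest_return,food_touch
#'   per-event signed values.
#' @return Named numeric vector keyed by event kind.
#' @export
colony_costs <- function(rotation = -0.02, pheromone_drop = -0.05,
                         movement = -0.25, resting = -0.5,
                         nest_return = 220, food_touch = 1.5) {
  c(rotation = rotation, pheromone_drop = pheromone_drop,
    movement = movement, resting = resting,
    nest_return = nest_return, food_touch = food_touch)
}

#' Score a colony event log
#'
#' Sums the signed per-event constants over a timestamped event log
#' (columns `t`, `ant_id`, `event`): rewards for nest returns and food
#' touches minus the accumulated action costs. Additive over
#' concatenated logs.
#'
#' @param log data frame with columns `t`, `ant_id`, `event`, or a
#'   character vector of event kinds.
#' @param costs a [colony_costs()] vector.
#' @return Scalar colony fitness.
#' @export
colony_fitness <- function(log, costs = colony_costs()) {
  events <- if (is.data.frame(log)) as.character(log$event) else as.character(log)
  if (length(events) == 0L) return(0)
  unknown <- setdiff(unique(events), names(costs))
  if (length(unknown) > 0L) {
    stop("unknown event kind(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(costs[events])
}

#' Read a colony event log from CSV
#'
#' Expected columns `t`, `ant_id`, `event`, so external agent-based
#' simulations can be scored with [colony_fitness()].
#'
#' @param path CSV file path.
#' @return A data frame with the three columns.
#' @export
read_event_log <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "ant_id", "event")
  if (!all(need %in% names(df))) {
    stop("event log must have columns t, ant_id, event", call. = FALSE)
  }
  df[need]
}

#' Pearson product-moment correlation
#'
#' `Cov(x, y) / (sd(x) * sd(y))`. Zero variance in either input is an
#' error (flagged rather than silently returned as 0 or NA).
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return Correlation in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("pearson needs two equal-length vectors of length >= 2", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("pearson undefined for zero-variance input", call. = FALSE)
  }
  cov(x, y) / (sd(x) * sd(y))
}

#' Functional-vs-structural connectivity fitness
#'
#' Two steps: (1) the functional connectivity (FC) matrix is the pairwise
#' Pearson correlation of the regional time series; (2) the structural
#' connectivity (SC) is normalized by its maximum entry and the fitness is
#' the Pearson correlation between the upper-triangular off-diagonal
#' entries of FC and of normalized SC (the FC diagonal is identically 1
#' and carries no information). Invariant under a simultaneous
#' permutation of regions in SC and the series.
#'
#' @param sc `n x n` nonnegative structural connectivity matrix with zero
#'   diagonal.
#' @param series `n x t_steps` matrix of regional activity time series.
#' @return Scalar fitness in [-1, 1].
#' @export
fc_sc_fitness <- function(sc, series) {
  sc <- as.matrix(sc)
  series <- as.matrix(series)
  n <- nrow(sc)
  stopifnot(ncol(sc) == n, nrow(series) == n, n >= 3L)
  if (any(sc < 0)) stop("SC must be nonnegative", call. = FALSE)
  if (any(apply(series, 1L, sd) == 0)) {
    stop("pearson undefined for zero-variance input (constant region series)",
         call. = FALSE)
  }
  fc <- cor(t(series))
  sc_norm <- sc / max(sc)
  ut <- upper.tri(sc, diag = FALSE)
  pearson(fc[ut], sc_norm[ut])
}

#' Maximum-position fitness for a mountain-car episode
#'
#' The fitness of an episode is the highest horizontal position the car
#' reached; reaching the goal yields 0.5.
#'
#' @param positions nonempty numeric vector of per-step car positions.
#' @return `max(positions)`.
#' @export
mc_fitness <- function(positions) {
  if (length(positions) == 0L) stop("empty position trace", call. = FALSE)
  max(positions)
}
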