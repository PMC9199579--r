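#' One ensemble Kalman inversion update
#'
#' Derivative-free update of an ensemble of parameter vectors toward a
#' target observation, driven entirely by ensemble statistics. Each member
#' `u_j` moves by
#' `u_j <- u_j + C_ud (C_dd + gamma I)^-1 (target - g(u_j))`,
#' where `C_ud` is the cross-covariance between parameters and model
#' predictions and `C_dd` the prediction covariance, both with population
#' (1/n) normalization over the ensemble. `gamma > 0` regularizes the solve
#' (the analogue of a learning rate: smaller gamma, larger steps) and makes
#' `C_dd + gamma I` symmetric positive definite, so the system is solved by
#' Cholesky factorization. Parameters are expected pre-normalized to [0, 1]
#' by the caller (see [optimizer_enkf()]).
#'
#' @param ensemble `n_ens x d` matrix, one parameter vector per row.
#' @param predictions `n_ens x k` matrix of model outputs per member.
#' @param target length-`k` observation vector.
#' @param gamma positive regularization constant.
#' @return The updated `n_ens x d` ensemble matrix.
#' @export
enkf_update <- function(ensemble, predictions, target, gamma) {
  ensemble <- as.matrix(ensemble)
  predictions <- as.matrix(predictions)
  n <- nrow(ensemble)
  if (n < 2L) stop("ensemble Kalman update needs at least 2 members", call. = FALSE)
  if (nrow(predictions) != n) stop("predictions must have one row per member", call. = FALSE)
  if (length(target) != ncol(predictions)) {
    stop("target length must match prediction dimension", call. = FALSE)
  }
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0", call. = FALSE)

  u_c <- sweep(ensemble, 2L, colMeans(ensemble))
  g_c <- sweep(predictions, 2L, colMeans(predictions))
  c_ud <- crossprod(u_c, g_c) / n           # d x k
  c_dd <- crossprod(g_c) / n                # k x k
  a <- c_dd + diag(gamma, ncol(c_dd))
  residual <- sweep(-predictions, 2L, as.numeric(target), `+`)  # n x k
  # u_j += C_ud A^-1 r_j for all j at once: ensemble + r A^-1 C_ud'
  ch <- chol(a)
  ensemble + residual %*% backsolve(ch, backsolve(ch, t(c_ud), transpose = TRUE))
}

#' Rank-based replacement of the worst ensemble members
#'
#' The fitness ranking is used to replace the worst `floor(fraction * n)`
#' members with copies of the best `floor(fraction * n)` members, paired
#' rank-to-rank (worst gets a copy of the best, second-worst of the
#' second-best, ...). Gaussian noise of scale `perturb_scale` is added to
#' each replacement to widen the search around good solutions. All other
#' members are untouched.
#'
#' @param ensemble `n_ens x d` parameter matrix.
#' @param fitnesses length-`n_ens` scalar fitness vector (larger is better).
#' @param fraction fraction of the ensemble to replace, in [0, 0.5].
#' @param perturb_scale standard deviation of the replacement noise.
#' @return The modified ensemble matrix.
#' @export
rank_replace_perturb <- function(ensemble, fitnesses, fraction, perturb_scale) {
  ensemble <- as.matrix(ensemble)
  n <- nrow(ensemble)
  stopifnot(length(fitnesses) == n, fraction >= 0, fraction <= 0.5)
  k <- floor(fraction * n)
  if (k < 1L) return(ensemble)
  ord <- order(fitnesses, decreasing = TRUE)  # best first
  best <- ord[seq_len(k)]
  worst <- rev(ord)[seq_len(k)]               # worst first
  noise <- matrix(rnorm(k * ncol(ensemble), sd = perturb_scale), nrow = k)
  ensemble[worst, ] <- ensemble[best, , drop = FALSE] + noise
  ensemble
}

#' Ensemble Kalman inversion optimizer (with rank-replace-perturb)
#'
#' Outer-loop optimizer for optimizees that, in addition to a fitness
#' vector, expose model predictions: the optimizee must provide a
#' `predict(individual, seed)` function returning the observation-space
#' output (for the reservoir classifier, the concatenated softmax vectors
#' over the presentation batch) and a `target` vector. Parameters are
#' mapped to [0, 1] using the fixed bounds declared in `normalize_bounds`
#' (stable across generations), updated by [enkf_update()], de-normalized,
#' and finally the worst members are replaced via [rank_replace_perturb()].
#'
#' @param gamma regularization constant, > 0.
#' @param replace_fraction fraction of members replaced per generation.
#' @param perturb_scale replacement noise scale, in raw parameter units.
#' @param normalize_bounds length-2 `(low, high)` used for the [0, 1]
#'   mapping; defaults to the spec bounds of each block.
#' @param predict_fn,target prediction function and observation target; may
#'   also be supplied by the optimizee (`optimizee$predict`,
#'   `optimizee$target`) via [run_experiment()].
#' @return An optimizer object.
#' @export
optimizer_enkf <- function(gamma = 0.5, replace_fraction = 0.1,
                           perturb_scale = 0, normalize_bounds = NULL,
                           predict_fn = NULL, target = NULL) {
  stopifnot(gamma > 0, replace_fraction >= 0, replace_fraction <= 0.5,
            perturb_scale >= 0)
  structure(list(gamma = gamma, replace_fraction = replace_fraction,
                 perturb_scale = perturb_scale,
                 normalize_bounds = normalize_bounds,
                 predict_fn = predict_fn, target = target),
            class = c("optimizer_enkf", "optimizer"))
}

.enkf_bounds <- function(opt, spec) {
  d <- spec_dimension(spec)
  if (!is.null(opt$normalize_bounds)) {
    list(low = rep(opt$normalize_bounds[1L], d),
         high = rep(opt$normalize_bounds[2L], d))
  } else {
    low <- unlist(lapply(spec$entries, function(e) rep(e$low, e$shape)))
    high <- unlist(lapply(spec$entries, function(e) rep(e$high, e$shape)))
    list(low = unname(low), high = unname(high))
  }
}

#' @export
opt_step.optimizer_enkf <- function(opt, state, population, records, spec, generation) {
  if (is.null(opt$predict_fn) || is.null(opt$target)) {
    stop("optimizer_enkf needs predict_fn and target (model predictions)", call. = FALSE)
  }
  m <- population_matrix(population, spec)
  b <- .enkf_bounds(opt, spec)
  norm <- sweep(sweep(m, 2L, b$low), 2L, b$high - b$low, `/`)
  predictions <- do.call(rbind, lapply(seq_along(population), function(i) {
    as.numeric(opt$predict_fn(population[[i]], records[[i]]$seed))
  }))
  norm <- enkf_update(norm, predictions, opt$target, opt$gamma)
  m <- sweep(sweep(norm, 2L, b$high - b$low, `*`), 2L, b$low, `+`)
  fs <- vapply(records, `[[`, numeric(1), "scalar_fitness")
  m <- rank_replace_perturb(m, fs, opt$replace_fraction, opt$perturb_scale)
  list(state = state, population = matrix_population(m, spec, generation))
}
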