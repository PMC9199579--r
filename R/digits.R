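#' Generate synthetic high-contrast digit images
#'
#' Desk-scale stand-in for a handwritten-digit set: three (or more)
#' distinct geometric glyph templates (ring, vertical bar, stacked
#' stripes, ...) rendered on a small canvas at intensity 255, jittered by
#' up to 2 pixels per sample, with salt noise (each pixel replaced by a
#' uniform random intensity with probability `noise`). The classes are
#' balanced and linearly well separated: a pixel-space nearest-centroid
#' classifier resolves them almost perfectly at moderate noise.
#'
#' @param n_per_class images per class.
#' @param n_classes number of classes (2-4 glyphs available).
#' @param n_pixels pixels per image; must factor into a canvas of at
#'   least 3 rows (768 gives 24 x 32).
#' @param noise salt-noise probability per pixel.
#' @return List with `images` (`n x n_pixels` matrix, values in
#'   [0, 255]), `labels` (integer classes 1..n_classes) and `canvas`
#'   (`c(rows, cols)`).
#' @export
synthetic_digits <- function(n_per_class, n_classes = 3L, n_pixels = 768L,
                             noise = 0.1) {
  stopifnot(n_classes >= 2L, n_classes <= 4L, n_per_class >= 1L)
  dims <- .canvas_dims(n_pixels)
  h <- dims[1L]; w <- dims[2L]
  glyphs <- list(.glyph_ring, .glyph_bar, .glyph_stripes, .glyph_cross)

  n_total <- n_per_class * n_classes
  labels <- rep(seq_len(n_classes), each = n_per_class)
  images <- matrix(0, n_total, n_pixels)
  for (i in seq_len(n_total)) {
    dx <- sample(-2:2, 1L); dy <- sample(-2:2, 1L)
    mask <- glyphs[[labels[i]]](h, w, dx, dy)
    img <- as.numeric(mask) * 255
    salt <- runif(n_pixels) < noise
    img[salt] <- runif(sum(salt), 0, 255)
    images[i, ] <- img
  }
  perm <- sample.int(n_total)
  list(images = images[perm, , drop = FALSE], labels = labels[perm],
       canvas = c(h, w))
}

.canvas_dims <- function(n_pixels) {
  divs <- which(n_pixels %% seq_len(n_pixels) == 0)
  target <- sqrt(n_pixels * 3 / 4)
  h <- divs[which.min(abs(divs - target))]
  if (h < 3L || n_pixels / h < 3L) {
    stop("n_pixels does not factor into a usable canvas", call. = FALSE)
  }
  c(h, n_pixels / h)
}

.glyph_grid <- function(h, w, dx, dy) {
  r <- matrix(seq_len(h), h, w) + dy
  c <- matrix(seq_len(w), h, w, byrow = TRUE) + dx
  list(r = (r - (h + 1) / 2) / h, c = (c - (w + 1) / 2) / w)
}

.glyph_ring <- function(h, w, dx, dy) {
  g <- .glyph_grid(h, w, dx, dy)
  d <- sqrt(g$r^2 + g$c^2)
  d > 0.2 & d < 0.38
}

.glyph_bar <- function(h, w, dx, dy) {
  g <- .glyph_grid(h, w, dx, dy)
  abs(g$c) < 0.08 & abs(g$r) < 0.42
}

.glyph_stripes <- function(h, w, dx, dy) {
  g <- .glyph_grid(h, w, dx, dy)
  (abs(g$r - 0.3) < 0.07 | abs(g$r + 0.3) < 0.07) & abs(g$c) < 0.35
}

.glyph_cross <- function(h, w, dx, dy) {
  g <- .glyph_grid(h, w, dx, dy)
  (abs(g$r) < 0.07 | abs(g$c) < 0.07) & abs(g$r) < 0.42 & abs(g$c) < 0.42
}

#' Nearest-centroid accuracy on an image set
#'
#' Leave-nothing-out nearest-centroid classification in pixel space; used
#' as the separability check for [synthetic_digits()].
#'
#' @param images `n x p` image matrix.
#' @param labels integer class labels.
#' @return Fraction of images assigned to their own class centroid.
#' @export
centroid_accuracy <- function(images, labels) {
  classes <- sort(unique(labels))
  centroids <- t(vapply(classes, function(k) {
    colMeans(images[labels == k, , drop = FALSE])
  }, numeric(ncol(images))))
  pred <- apply(images, 1L, function(x) {
    classes[which.min(colSums((t(centroids) - x)^2))]
  })
  mean(pred == labels)
}

#' Train the reservoir readout with ensemble Kalman inversion
#'
#' The full classification pipeline at configurable scale: a fixed random
#' reservoir is built once; an ensemble of readout weight vectors (the
#' reservoir-to-output synapses, the only trainable parameters) is
#' evaluated per generation on a batch of synthetic digit images
#' ([run_digit_protocol()] then [softmax()] of the output-cluster rates);
#' the classification fitness is `1 - L` with `L` the mean squared error
#' against the one-hot labels; the ensemble is updated by [enkf_update()]
#' against the concatenated one-hot targets and the worst members are
#' refreshed by [rank_replace_perturb()]. Every tenth generation the best
#' member is additionally scored on a held-out batch.
#'
#' @param scale reservoir scale (1 = 2000 reservoir neurons).
#' @param ensemble_size number of ensemble members.
#' @param n_generations EnKF generations.
#' @param gamma EnKF regularization.
#' @param replace_fraction,perturb_scale rank-replacement settings
#'   (perturbation in readout weight units, mV).
#' @param batch_size images presented per generation.
#' @param n_train,n_test per-class sizes of the training and held-out
#'   pools.
#' @param noise salt-noise level of the synthetic digits.
#' @param softmax_temp temperature (Hz) dividing the cluster rates before
#'   the softmax.
#' @param seed experiment seed.
#' @param dt integration step (ms).
#' @param weight_bounds fixed readout-weight bounds (mV) used for the
#'   EnKF [0, 1] normalization.
#' @param protocol a [digit_protocol()].
#' @param verbose print per-generation best fitness.
#' @return List with `best_fitness_history` (per generation),
#'   `mean_fitness_history`, `test_history` (generation, fitness),
#'   `best_weights`, and `net`.
#' @export
train_reservoir <- function(scale = 0.1, ensemble_size = 20L,
                            n_generations = 30L, gamma = 0.5,
                            replace_fraction = 0.1, perturb_scale = 0.5,
                            batch_size = 10L, n_train = 30L, n_test = 10L,
                            noise = 0.1, softmax_temp = 5, seed = 1L,
                            dt = 0.1, weight_bounds = c(-2.5, 2.5),
                            protocol = digit_protocol(), verbose = FALSE) {
  n_classes <- 3L
  set.seed(derive_seed(seed, 0L, 11L))
  net <- build_reservoir(scale, n_classes = n_classes)
  readout <- attr(net, "readout")
  res_exc <- attr(net, "res_exc")
  n_px <- attr(net, "n_pixels")
  train <- synthetic_digits(n_train, n_classes, n_pixels = n_px, noise = noise)
  test <- synthetic_digits(n_test, n_classes, n_pixels = n_px, noise = noise)

  # per-member readout init: small weights signed by source type
  src_exc <- net$synapses$pre[readout] %in% res_exc
  d <- length(readout)
  init_member <- function() {
    ifelse(src_exc, rnorm(d, 0.7, 1), rnorm(d, -0.9, 1))
  }
  ensemble <- t(vapply(seq_len(ensemble_size), function(i) init_member(),
                       numeric(d)))

  eval_member <- function(w, batch, member_seed) {
    net$synapses$weight[readout] <- w
    set.seed(member_seed)
    rates <- run_digit_protocol(net, batch$images, protocol, dt)
    probs <- t(apply(rates / softmax_temp, 1L, softmax))
    list(probs = probs, rates = rates)
  }
  batch_fitness <- function(probs, labels) {
    1 - mean(vapply(seq_along(labels), function(i) {
      y <- as.numeric(seq_len(n_classes) == labels[i])
      mean((y - probs[i, ])^2)
    }, numeric(1)))
  }

  best_hist <- numeric(n_generations)
  mean_hist <- numeric(n_generations)
  test_hist <- list()
  best_weights <- NULL; best_seen <- -Inf
  for (g in seq_len(n_generations)) {
    set.seed(derive_seed(seed, g, 13L))
    idx <- sample.int(nrow(train$images), batch_size)
    batch <- list(images = train$images[idx, , drop = FALSE],
                  labels = train$labels[idx])
    # image-major layout, matching the concatenated per-image softmax rows
    target <- as.numeric(vapply(batch$labels, function(l) {
      as.numeric(seq_len(n_classes) == l)
    }, numeric(n_classes)))

    # common random numbers: one simulation seed per generation for all
    # members, so prediction differences reflect weight differences only
    sim_seed <- derive_seed(seed, g, 100L)
    outs <- lapply(seq_len(ensemble_size), function(m) {
      eval_member(ensemble[m, ], batch, sim_seed)
    })
    predictions <- do.call(rbind, lapply(outs, function(o) as.numeric(t(o$probs))))
    fitnesses <- vapply(outs, function(o) batch_fitness(o$probs, batch$labels),
                        numeric(1))
    best_hist[g] <- max(fitnesses)
    mean_hist[g] <- mean(fitnesses)
    if (best_hist[g] > best_seen) {
      best_seen <- best_hist[g]
      best_weights <- ensemble[which.max(fitnesses), ]
    }
    if (verbose) {
      message(sprintf("generation %d: best %.3f mean %.3f", g,
                      best_hist[g], mean_hist[g]))
    }
    if (g %% 10L == 0L) {
      set.seed(derive_seed(seed, g, 17L))
      tidx <- sample.int(nrow(test$images), batch_size)
      tout <- eval_member(ensemble[which.max(fitnesses), ],
                          list(images = test$images[tidx, , drop = FALSE]),
                          derive_seed(seed, g, 19L))
      test_hist[[length(test_hist) + 1L]] <-
        c(generation = g,
          fitness = batch_fitness(tout$probs, test$labels[tidx]))
    }
    if (g == n_generations) break
    lo <- weight_bounds[1L]; hi <- weight_bounds[2L]
    norm <- (pmin(pmax(ensemble, lo), hi) - lo) / (hi - lo)
    norm <- enkf_update(norm, predictions, target, gamma)
    ensemble <- norm * (hi - lo) + lo
    set.seed(derive_seed(seed, g, 23L))
    ensemble <- rank_replace_perturb(ensemble, fitnesses, replace_fraction,
                                     perturb_scale)
    ensemble <- pmin(pmax(ensemble, lo), hi)
  }
  list(best_fitness_history = best_hist, mean_fitness_history = mean_hist,
       test_history = do.call(rbind, test_hist),
       best_weights = best_weights, net = net)
}
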