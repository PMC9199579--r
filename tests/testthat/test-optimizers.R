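# evolution strategies ------------------------------------------------------

test_that("equal offspring fitness leaves the ES center unchanged", {
  cfg <- es_config(sigma = 0.2, learning_rate = 0.5, n_offspring = 6L)
  center <- c(1, -1)
  noises <- matrix(rnorm(12), 6)
  expect_equal(es_step(center, rep(3.3, 6), noises, cfg), center)
})

test_that("mirrored perturbations under a linear fitness recover the gradient direction", {
  cfg <- es_config(sigma = 0.1, learning_rate = 1, n_offspring = 2L)
  a <- c(2, -1, 0.5)
  eps <- c(0.3, 0.1, -0.2)
  noises <- rbind(eps, -eps)
  fs <- c(sum(a * (0.1 * eps)), sum(a * (-0.1 * eps)))
  new_center <- es_step(c(0, 0, 0), fs, noises, cfg)
  # the step is along +eps (the better mirror), i.e. sign-aligned with a'eps
  expect_gt(sum(new_center * eps) * sign(sum(a * eps)), 0)
})

test_that("the ES center drifts downhill on a 1-d bowl", {
  cfg <- es_config(sigma = 0.1, learning_rate = 0.5, n_offspring = 20L)
  set.seed(10)
  steps <- replicate(200, {
    center <- 1
    noises <- matrix(rnorm(20), 20)
    fs <- -(center + cfg$sigma * noises[, 1])^2
    es_step(center, fs, noises, cfg) - center
  })
  expect_lt(mean(steps), 0)
  expect_gt(mean(steps < 0), 0.9)
})

test_that("ES configuration rejects nonpositive sigma", {
  expect_error(es_config(sigma = 0), "sigma")
  expect_error(optimizer_es(sigma = -1), "sigma")
})

# gradient ascent ------------------------------------------------------------

test_that("probe regression recovers a linear gradient exactly", {
  cfg <- gd_config(learning_rate = 1, probe_scale = 0.1)
  a <- c(1.5, -2, 0.25)
  center <- c(0.2, 0.1, 0)
  set.seed(3)
  probes <- sweep(matrix(rnorm(30, sd = 0.1), 10), 2, center, `+`)
  fs <- as.numeric(probes %*% a) + 7
  expect_equal(gradient_step(center, probes, fs, cfg), center + a,
               tolerance = 1e-8)
  cfg0 <- gd_config(learning_rate = 0, probe_scale = 0.1)
  expect_equal(gradient_step(center, probes, fs, cfg0), center)
})

test_that("rank-deficient probe sets fall back to the least-norm gradient", {
  cfg <- gd_config(learning_rate = 1, probe_scale = 0.1, n_probe = 2L)
  center <- c(0, 0, 0)
  probes <- rbind(c(0.1, 0, 0), c(-0.1, 0, 0))
  fs <- c(0.1, -0.1)  # gradient (1, 0, 0) in the probed subspace
  expect_equal(gradient_step(center, probes, fs, cfg), c(1, 0, 0),
               tolerance = 1e-8)
})

test_that("repeated gradient steps descend a quadratic bowl in expectation", {
  cfg <- gd_config(learning_rate = 0.2, probe_scale = 0.05, n_probe = 8L)
  set.seed(4)
  dists <- replicate(30, {
    center <- c(1, 1)
    d <- numeric(20)
    for (s in 1:20) {
      probes <- sweep(matrix(rnorm(16, sd = cfg$probe_scale), 8), 2, center, `+`)
      fs <- -rowSums(probes^2)
      center <- gradient_step(center, probes, fs, cfg)
      d[s] <- sqrt(sum(center^2))
    }
    d
  })
  avg <- rowMeans(dists)
  expect_true(all(diff(avg) < 0.02))
  expect_lt(avg[20], 0.2)
})

# multi-gradient ascent ------------------------------------------------------

test_that("the dominant combination becomes the next cloud center", {
  cfg <- gd_config(learning_rate = 0, mode = "multi", shrink_factor = 0.5)
  cloud <- make_cloud(c(0, 0), c(1, 1), 16)
  fs <- rep(0, nrow(cloud$points)); fs[7] <- 10
  out <- multi_gradient_step(list(cloud), list(fs), cfg)
  expect_equal(out[[1]]$center, unname(cloud$points[7, ]))
  expect_equal(out[[1]]$half_range, c(0.5, 0.5))
  expect_equal(nrow(out[[1]]$points), 16)
  expect_error(multi_gradient_step(list(list(points = NULL)), list(numeric(0)),
                                   cfg), "empty")
})

test_that("clouds are evenly spaced grids of the requested size", {
  cloud <- make_cloud(c(1, 2), c(0.5, 0.5), 64)
  expect_equal(dim(cloud$points), c(64, 2))
  expect_equal(sort(unique(cloud$points[, 1])), seq(0.5, 1.5, length.out = 8))
})

# simulated annealing --------------------------------------------------------

test_that("the acceptance rule is greedy for improvements and calibrated for losses", {
  expect_true(sa_accept(0, 1, 0.5))
  expect_true(sa_accept(0, 0, 1e-9))
  set.seed(5)
  acc <- mean(replicate(10000, sa_accept(0, -1, 1)))
  expect_equal(acc, exp(-1), tolerance = 0.05)
  set.seed(5)
  expect_false(any(replicate(200, sa_accept(0, -1, 1e-6))))
})

test_that("cooling schedules have the declared forms", {
  cfg <- sa_config(initial_temperature = 2, cooling_factor = 0.9,
                   n_generations = 10L)
  expect_equal(sa_cooling(0, cfg), 2)
  expect_equal(sa_cooling(3, cfg), 2 * 0.9^3)
  cfg_lin <- sa_config("linear", initial_temperature = 2, n_generations = 10L)
  expect_equal(sa_cooling(5, cfg_lin), 1)
  cfg_log <- sa_config("logarithmic", initial_temperature = 2)
  expect_equal(sa_cooling(0, cfg_log), 2)
  expect_error(sa_config(initial_temperature = 0), "temperature")
})

# cross-entropy --------------------------------------------------------------

test_that("cross-entropy concentrates on a degenerate elite", {
  set.seed(6)
  m <- matrix(rnorm(40), 20)
  m[1:5, ] <- matrix(rep(c(3, -2), each = 5), 5)
  fs <- c(rep(10, 5), rep(0, 15))
  out <- ce_step(m, fs, ce_config(elite_fraction = 0.25, smoothing = 0,
                                  cov_floor = 1e-10))
  expect_equal(out$mean, c(3, -2), tolerance = 1e-6)
  expect_lt(max(abs(sweep(out$population, 2, c(3, -2)))), 0.01)
})

test_that("elite fraction one refits the population moments", {
  set.seed(7)
  m <- matrix(rnorm(200), 100)
  out <- ce_step(m, rnorm(100), ce_config(elite_fraction = 1, smoothing = 0,
                                          cov_floor = 0))
  expect_equal(out$mean, colMeans(m))
  expect_equal(out$cov, cov(m) * 99 / 100, tolerance = 1e-12)
})

test_that("cross-entropy converges on a 1-d bowl", {
  spec <- param_spec(x = list(low = -2, high = 2))
  optee <- list(spec = spec, simulate = function(ind, seed) -(ind$values$x - 0.7)^2)
  cfg <- experiment_config(optee, optimizer_ce(elite_fraction = 0.3),
                           n_pop = 40L, n_generations = 30L, seed = 8L)
  traj <- run_experiment(cfg)
  expect_equal(trajectory_best(traj)$individual$values$x, 0.7, tolerance = 0.01 / 0.7)
})

# grid search ----------------------------------------------------------------

test_that("grids include both endpoints and multiply out", {
  spec1 <- param_spec(x = list(low = 0, high = 1))
  pop <- grid_generate(spec1, 3L)
  expect_equal(sort(vapply(pop, function(p) p$values$x, numeric(1))),
               c(0, 0.5, 1))
  spec2 <- param_spec(a = list(low = 0, high = 1), b = list(low = -1, high = 1))
  expect_length(grid_generate(spec2, 20L), 400)
})

test_that("the combination cap reports the offending count", {
  spec <- param_spec(w = list(shape = 250, low = -20, high = 20),
                     d = list(shape = 250, low = 1, high = 6, kind = "integer"))
  expect_error(grid_generate(spec, 20L), "20\\^500")
})
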