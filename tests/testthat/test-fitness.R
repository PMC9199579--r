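test_that("softmax matches direct evaluation and its invariances", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3), tolerance = 1e-12)
  x <- c(1, 2, 3)
  expect_equal(softmax(x), exp(x) / sum(exp(x)), tolerance = 1e-12)
  expect_equal(softmax(x), c(0.0900, 0.2447, 0.6652), tolerance = 1e-3)
  set.seed(1)
  for (i in 1:25) {
    v <- rnorm(sample(2:8, 1), sd = 10)
    s <- softmax(v)
    expect_equal(sum(s), 1, tolerance = 1e-12)
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(softmax(v + rnorm(1) * 0 + 57.3), s, tolerance = 1e-12)
  }
  expect_equal(softmax(c(1e6, 0)), c(1, 0))  # shift-safe at extreme inputs
  expect_error(softmax(numeric(0)), "empty")
  expect_error(softmax(c(1, Inf)), "finite")
})

test_that("classification fitness is one minus the mean squared error", {
  expect_equal(mse_fitness(c(1, 0, 0), c(1, 0, 0)), 1)
  expect_equal(mse_fitness(c(1, 0, 0), c(0.5, 0.25, 0.25)), 0.875,
               tolerance = 1e-12)
  expect_equal(mse_fitness(c(1, 0, 0), c(0, 1, 0)), 1 / 3, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:20) {
    y <- as.numeric(1:4 == sample(4, 1)); p <- runif(4)
    expect_lte(mse_fitness(y, p), 1)
  }
  expect_error(mse_fitness(c(1, 0), c(1, 0, 0)), "length")
})

test_that("trace square loss is the negated 1/T^2 sum", {
  dt <- 0.5
  ref <- voltage_trace(c(-70, -65, -60, -65, -70), dt)
  expect_equal(trace_square_loss(ref, ref), 0)
  t_steps <- 4
  off <- voltage_trace(ref$samples + 2, dt)
  expect_equal(trace_square_loss(ref, off), -sum(rep(4, 5)) / t_steps^2,
               tolerance = 1e-12)
  off2 <- voltage_trace(ref$samples + 4, dt)
  expect_equal(trace_square_loss(ref, off2), 4 * trace_square_loss(ref, off),
               tolerance = 1e-12)
  expect_equal(trace_square_loss(ref, off, normalization = "mean"),
               -sum(rep(4, 5)) / t_steps, tolerance = 1e-12)
  expect_error(trace_square_loss(ref, voltage_trace(c(1, 2), dt)), "length")
  expect_error(trace_square_loss(ref, voltage_trace(ref$samples, 1)), "dt")
})

test_that("spike features follow the threshold-selection definition", {
  dt <- 1
  ref <- voltage_trace(c(0, 2, 0), dt)
  sim <- voltage_trace(c(0, 1, 0), dt)
  expect_equal(spike_feature_fitness(ref, ref, 1), c(L = 0, S = 0))
  out <- spike_feature_fitness(ref, sim, 1)
  expect_equal(out[["L"]], 1 / 3, tolerance = 1e-12)
  expect_equal(out[["S"]], 1, tolerance = 1e-12)
  expect_equal(spike_feature_fitness(ref, sim, 10)[["S"]], 0)
  expect_gte(spike_feature_fitness(sim, ref, 0.5)[["L"]], 0)
})

test_that("per-stimulus features interleave into the fitness vector", {
  pairs <- list(c(0.1, -0.2), c(0.3, 0.4))
  fv <- stimulus_fitness_vector(pairs)
  expect_equal(fv, c(0.1, -0.2, 0.3, 0.4))
  expect_equal(stimulus_fitness_vector(list(c(0, 0), c(0, 0))), rep(0, 4))
  expect_equal(weighted_fitness(fv, c(1, 0, 1, 0)), 0.4)
})

test_that("colony fitness sums the reference per-event constants", {
  expect_equal(colony_fitness(character(0)), 0)
  expect_equal(colony_fitness(c("nest_return", "food_touch")), 221.5)
  expect_equal(colony_fitness(c(rep("movement", 4), "rotation", "resting")),
               -(4 * 0.25 + 0.02 + 0.5), tolerance = 1e-12)
  set.seed(3)
  kinds <- names(colony_costs())
  l1 <- sample(kinds, 20, replace = TRUE)
  l2 <- sample(kinds, 30, replace = TRUE)
  expect_equal(colony_fitness(c(l1, l2)),
               colony_fitness(l1) + colony_fitness(l2), tolerance = 1e-12)
  expect_error(colony_fitness("teleport"), "unknown event")
})

test_that("event logs round-trip through CSV for external scoring", {
  df <- data.frame(t = c(1, 2, 2), ant_id = c(1, 1, 2),
                   event = c("movement", "food_touch", "nest_return"))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  log <- read_event_log(path)
  expect_equal(colony_fitness(log), -0.25 + 1.5 + 220)
})

test_that("pearson matches the moment definition and flags degeneracy", {
  expect_equal(pearson(1:5, 1:5), 1)
  expect_equal(pearson(1:5, -(1:5)), -1)
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  expect_equal(pearson(x, y), cor(x, y), tolerance = 1e-12)
  expect_equal(pearson(x, y), 0.9820, tolerance = 1e-4)
  expect_error(pearson(c(1, 1, 1), 1:3), "zero-variance")
  expect_error(pearson(1, 2), "length")
})

test_that("fc_sc_fitness scores a constructed perfect match at 1", {
  set.seed(4)
  n <- 6
  sc <- modular_sc(n, 2)
  # target correlation matrix proportional to normalized SC off-diagonals
  r <- diag(n) + 0.3 * sc / max(sc)
  # whiten a random series, then color it so the sample correlation is exactly r
  z <- matrix(rnorm(n * 200), n)
  z <- z - rowMeans(z)
  zw <- solve(t(chol(cov(t(z))))) %*% z      # whitened: sample covariance I
  series <- t(chol(r)) %*% zw                # colored: sample correlation r
  expect_equal(fc_sc_fitness(sc, series), 1, tolerance = 1e-8)
})

test_that("fc_sc_fitness is invariant under region permutation and near zero under the null", {
  set.seed(5)
  sc <- modular_sc(8, 2)
  series <- matrix(rnorm(8 * 300), 8)
  f <- fc_sc_fitness(sc, series)
  perm <- sample(8)
  expect_equal(fc_sc_fitness(sc[perm, perm], series[perm, ]), f,
               tolerance = 1e-12)
  # null scale: with n regions there are n(n-1)/2 FC entries, so the null
  # correlation has sd ~ 1/sqrt(n(n-1)/2 - 2); 20 regions keep max|r| small
  nulls <- vapply(1:20, function(i) {
    fc_sc_fitness(modular_sc(20, 2), matrix(rnorm(20 * 500), 20))
  }, numeric(1))
  expect_lt(max(abs(nulls)), 0.2)
  expect_lt(mean(abs(nulls)), 0.1)
  expect_error(fc_sc_fitness(sc, matrix(1, 8, 10)), "zero-variance")
})

test_that("mountain-car fitness is the maximum position", {
  expect_equal(mc_fitness(c(-0.5, -0.3, 0.1)), 0.1)
  expect_equal(mc_fitness(rep(-0.42, 7)), -0.42)
  expect_error(mc_fitness(numeric(0)), "empty")
})
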