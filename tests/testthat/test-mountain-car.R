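test_that("the environment update matches the declared physics", {
  out <- mc_step(list(position = -0.5, velocity = 0), 2L)
  expect_equal(out$state$velocity, 0.001 - 0.0025 * cos(3 * -0.5),
               tolerance = 1e-12)
  expect_equal(out$state$velocity, 0.000823, tolerance = 1e-3)
  expect_false(out$done)
  expect_true(mc_step(list(position = 0.499, velocity = 0.07), 2L)$done)
  expect_false(mc_step(list(position = 0.42, velocity = 0.01), 2L)$done)
  expect_error(mc_step(list(position = 0, velocity = 0), 5L))
})

test_that("state stays within bounds over random rollouts", {
  set.seed(1)
  st <- mc_reset()
  expect_true(st$position >= -0.6 && st$position <= -0.4)
  expect_equal(st$velocity, 0)
  for (i in 1:500) {
    st <- mc_step(st, sample(0:2, 1))$state
    expect_true(st$position >= -1.2 && st$position <= 0.6)
    expect_true(abs(st$velocity) <= 0.07)
  }
})

test_that("the compiled episode loop equals the step-by-step composition", {
  set.seed(2)
  for (k in 1:4) {
    w <- runif(315, -20, 20)
    start <- list(position = runif(1, -0.6, -0.4), velocity = 0)
    a <- run_mc_episode(w, 60, start = start, engine = "r")
    b <- run_mc_episode(w, 60, start = start, engine = "cpp")
    expect_identical(a$positions, b$positions)
    expect_identical(a$actions, as.integer(b$actions))
    expect_identical(a$steps_to_goal, b$steps_to_goal)
  }
})

test_that("a dead network holds the default action and never reaches the goal", {
  start <- list(position = -0.5, velocity = 0)
  ep <- run_mc_episode(rep(0, 315), 110, start = start)
  expect_true(all(ep$actions == 1L))
  expect_true(is.na(ep$steps_to_goal))
  expect_lt(mc_fitness(ep$positions), 0.5)
})

test_that("episode fitness composes with the goal condition", {
  set.seed(3)
  for (k in 1:10) {
    ep <- run_mc_episode(runif(315, -20, 20), 110)
    if (!is.na(ep$steps_to_goal)) {
      expect_gte(mc_fitness(ep$positions), 0.5)
      expect_equal(ep$steps_to_goal, length(ep$positions))
    } else {
      expect_lt(mc_fitness(ep$positions), 0.5)
      expect_lte(length(ep$positions), 110)
    }
  }
})

test_that("a handcrafted momentum policy solves the task", {
  # push in the direction of travel: the two negative-velocity bins drive
  # the left action, the two nonnegative ones the right action
  w <- rep(0, 315)
  w[c((44 - 1) * 5 + 1, (45 - 1) * 5 + 1)] <- 20   # v < 0 -> hidden 1
  w[300 + 1] <- 20                                 # hidden 1 -> left
  w[c((46 - 1) * 5 + 2, (47 - 1) * 5 + 2)] <- 20   # v >= 0 -> hidden 2
  w[300 + 1 * 3 + 3] <- 20                         # hidden 2 -> right
  ep <- run_mc_episode(w, 200, start = list(position = -0.5, velocity = 0))
  expect_false(is.na(ep$steps_to_goal))
  expect_gte(mc_fitness(ep$positions), 0.5)
  ev <- mc_evaluate(w, n_episodes = 20L, max_steps = 200L, seed = 5L)
  expect_equal(ev$success_rate, 1)
})

test_that("policy evaluation counts unfinished episodes at the cap", {
  ev <- mc_evaluate(rep(0, 315), n_episodes = 5L, max_steps = 50L, seed = 1L)
  expect_equal(ev$mean_steps, 50)
  expect_equal(ev$success_rate, 0)
  expect_length(ev$steps, 5)
})
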