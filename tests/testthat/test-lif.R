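test_that("a silent network emits no spikes", {
  net <- one_neuron_net()
  rec <- simulate_network(net, NULL, 100, 0.1)
  expect_equal(rec$counts, 0L)
})

test_that("the simulator tracks the closed-form f-I curve within 2%", {
  p <- lif_params()
  net <- one_neuron_net(p)
  for (amp in c(18, 25, 40, 80)) {
    drv <- data.frame(neuron = 1L, start = 0, end = 2000, amplitude = amp)
    rec <- simulate_network(net, drv, 2000, 0.1)
    sim_rate <- rec$counts / 2
    expect_equal(sim_rate, lif_rate_closed_form(amp, p),
                 tolerance = 0.02, label = sprintf("rate at amp %g", amp))
  }
  # subthreshold drive stays silent
  sub <- data.frame(neuron = 1L, start = 0, end = 500, amplitude = 10)
  expect_equal(simulate_network(net, sub, 500, 0.1)$counts, 0L)
})

test_that("spike trains respect refractoriness and stay in the window", {
  p <- lif_params()
  net <- one_neuron_net(p)
  drv <- data.frame(neuron = 1L, start = 0, end = 500,
                    amplitude = lif_dc_for_rate(400, p))
  rec <- simulate_network(net, drv, 500, 0.1, record_times = TRUE)
  times <- rec$times[[1]]
  expect_gt(length(times), 10)
  expect_true(all(times > 0 & times <= 500))
  expect_true(all(diff(times) >= p$t_ref))
  expect_true(all(diff(times) > 0))
})

test_that("delayed synapses are causal", {
  p <- lif_params()
  syn <- data.frame(pre = 1L, post = 2L, weight = 30, delay = 25L)  # 2.5 ms
  net <- network_spec(2L, syn, params = p)
  drv <- data.frame(neuron = 1L, start = 0, end = 100, amplitude = 100)
  rec <- simulate_network(net, drv, 100, 0.1, record_times = TRUE)
  expect_gt(length(rec$times[[1]]), 0)
  expect_gt(length(rec$times[[2]]), 0)
  expect_gte(min(rec$times[[2]]), min(rec$times[[1]]) + 2.5)
})

test_that("chunked simulation with carried state equals a single run", {
  p <- lif_params()
  syn <- data.frame(pre = c(1L, 1L), post = c(2L, 2L), weight = c(8, 8),
                    delay = c(1L, 40L))
  net <- network_spec(2L, syn, params = p)
  drv <- function(t0, t1) data.frame(neuron = 1L, start = t0, end = t1,
                                     amplitude = 25)
  whole <- simulate_network(net, drv(0, 200), 200, 0.1)
  first <- simulate_network(net, drv(0, 100), 100, 0.1)
  second <- simulate_network(net, drv(0, 100), 100, 0.1, state = first$state)
  expect_equal(first$counts + second$counts, whole$counts)
  expect_equal(second$state$v, whole$state$v)
})

test_that("Poisson source neurons fire near their programmed rate", {
  net <- network_spec(1L, empty_synapses(), is_source = TRUE)
  drv <- data.frame(neuron = 1L, start = 0, end = 5000, amplitude = 80)
  set.seed(9)
  rec <- simulate_network(net, drv, 5000, 0.1)
  expect_equal(rec$counts / 5, 80, tolerance = 0.15)
  set.seed(9)
  rec2 <- simulate_network(net, drv, 5000, 0.1)
  expect_identical(rec$counts, rec2$counts)
})

test_that("background noise is reproducible under a seed and raises activity", {
  net <- one_neuron_net()
  set.seed(4)
  a <- simulate_network(net, NULL, 2000, 0.1, bg_rate = 200, bg_weight = 16)
  set.seed(4)
  b <- simulate_network(net, NULL, 2000, 0.1, bg_rate = 200, bg_weight = 16)
  expect_identical(a$counts, b$counts)
  expect_gt(a$counts, 0)
})

test_that("network validation catches bad synapse tables", {
  expect_error(network_spec(2L, data.frame(pre = 1L, post = 2L, weight = 1,
                                           delay = 0L)), "delay")
  expect_error(network_spec(2L, data.frame(pre = 1L, post = 3L, weight = 1,
                                           delay = 1L)))
  expect_error(lif_params(v_thr = -80), "threshold")
})

test_that("edge lists round-trip through CSV", {
  set.seed(2)
  net <- build_ant_brain(runif(250, -20, 20), sample(1:5, 250, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_network_csv(net, path)
  back <- read_network_csv(path)
  expect_equal(back, net$synapses)
})
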