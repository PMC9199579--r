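test_that("pixel intensities map affinely to [1, 100] Hz", {
  expect_equal(encode_pixels_to_rates(0), 1)
  expect_equal(encode_pixels_to_rates(255), 100)
  expect_equal(encode_pixels_to_rates(128), 1 + 99 * 128 / 255,
               tolerance = 1e-12)
  r <- encode_pixels_to_rates(0:255)
  expect_true(all(diff(r) > 0))
  expect_error(encode_pixels_to_rates(c(3, 300)), "255")
})

test_that("state binning follows the clamped floor rule", {
  expect_equal(bin_index(-1.2, -1.2, 0.6, 30L), 0L)
  expect_equal(bin_index(0.0, -1.2, 0.6, 30L), 20L)
  expect_equal(bin_index(0.6, -1.2, 0.6, 30L), 29L)
  expect_equal(bin_index(10, 0, 1, 4L), 3L)   # clamped above
  expect_equal(bin_index(-3, 0, 1, 4L), 0L)   # clamped below
  expect_error(bin_index(0, 1, 1, 4L), "low")
})

test_that("winner-take-all decodes argmax with declared tie and default rules", {
  expect_equal(winner_take_all(c(5, 2, 0)), 1L)
  expect_equal(winner_take_all(c(3, 3, 0)), 1L)
  expect_equal(winner_take_all(c(0, 0, 0), default = 2L), 2L)
})

test_that("the ant-brain builder realizes the fixed 250-synapse topology", {
  set.seed(1)
  w <- runif(250, -20, 20); d <- sample(1:5, 250, TRUE)
  net <- build_ant_brain(w, d)
  syn <- net$synapses
  expect_equal(nrow(syn), 250)
  hidden <- net$populations$hidden
  expect_equal(sum(syn$pre %in% 1:11 & syn$post %in% hidden), 110)
  expect_equal(sum(syn$pre == 12 & syn$post %in% hidden), 10)
  expect_equal(sum(syn$pre %in% hidden & syn$post %in% hidden), 90)
  expect_equal(sum(syn$pre %in% hidden & syn$post %in% net$populations$output), 40)
  expect_false(any(syn$pre == syn$post))
  expect_equal(syn$weight, w)  # stable documented ordering
  expect_error(build_ant_brain(w[-1], d), "250")
})

test_that("ant-brain weights and delays respect their bounds after clipping", {
  spec <- param_spec(w = list(shape = 250, low = -20, high = 20),
                     d = list(shape = 250, low = 1, high = 5, kind = "integer"))
  set.seed(2)
  ind <- new_individual(list(w = runif(250, -40, 40), d = runif(250, 0.4, 6.9)))
  ind <- apply_bounds(ind, spec)
  net <- build_ant_brain(ind$values$w, ind$values$d)
  expect_true(all(net$synapses$weight >= -20 & net$synapses$weight <= 20))
  expect_true(all(net$synapses$delay %in% 1:5))
})

test_that("the policy-network builder realizes the 60-5-3 topology", {
  set.seed(3)
  net <- build_mc_policy(runif(315, -20, 20))
  expect_equal(nrow(net$synapses), 315)
  expect_length(net$populations$input, 60)
  expect_length(net$populations$hidden, 5)
  expect_length(net$populations$output, 3)
  expect_error(build_mc_policy(runif(314)), "315")
})

test_that("the calibrated DC drive puts active inputs near the 500 Hz ceiling", {
  p <- lif_params()
  net <- build_mc_policy(rep(0, 315), params = p)
  dc <- attr(net, "input_dc")
  probe <- one_neuron_net(p)
  drv <- data.frame(neuron = 1L, start = 0, end = 1000, amplitude = dc)
  rec <- simulate_network(probe, drv, 1000, 0.1)
  expect_equal(rec$counts, 500, tolerance = 25 / 500)
})

test_that("the full-scale reservoir has the reference structure", {
  set.seed(4)
  net <- build_reservoir(1)
  expect_length(attr(net, "readout"), 28800)
  expect_length(net$populations$reservoir, 2000)
  expect_length(net$populations$input, 768)
  clusters <- net$populations[grep("^output_cluster_", names(net$populations))]
  expect_length(clusters, 3)
  expect_true(all(lengths(clusters) == 12))
  # no synapses across distinct output clusters
  syn <- net$synapses
  for (a in 1:3) for (b in 1:3) {
    if (a != b) {
      expect_equal(sum(syn$pre %in% clusters[[a]] & syn$post %in% clusters[[b]]), 0)
    }
  }
})

test_that("reservoir scaling preserves ratios and determinism", {
  set.seed(5); n1 <- build_reservoir(0.1)
  set.seed(5); n2 <- build_reservoir(0.1)
  expect_identical(n1$synapses, n2$synapses)
  expect_length(n1$populations$reservoir, 200)
  expect_length(n1$populations$input, 77)
  expect_length(attr(n1, "readout"), 80 * sum(grepl("^output_cluster_",
                                                    names(n1$populations))) *
                  length(n1$populations$output_cluster_1))
  expect_error(build_reservoir(0.01), "empty")
})

test_that("the digit protocol returns per-image cluster rates on schedule", {
  set.seed(6)
  net <- build_reservoir(0.1)
  n_px <- attr(net, "n_pixels")
  d <- synthetic_digits(4, 3, n_pixels = n_px, noise = 0.05)
  rates <- run_digit_protocol(net, d$images[1:3, ], dt = 0.2)
  expect_equal(dim(rates), c(3, 3))
  expect_equal(attr(rates, "total_time_ms"), 100 + 3 * 700)
  expect_true(all(rates >= 0))

  # zero readout weights decouple the output: near-background rates
  net0 <- net
  net0$synapses$weight[attr(net, "readout")] <- 0
  r0 <- run_digit_protocol(net0, d$images[1:2, ], dt = 0.2)
  expect_lt(mean(r0), mean(rates) / 2 + 5)
  bad <- matrix(0, 1, n_px + 20)
  expect_silent(run_digit_protocol(net, bad, dt = 0.2))  # truncates
  expect_error(run_digit_protocol(net, matrix(0, 1, 10), dt = 0.2), "pixels")
})
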