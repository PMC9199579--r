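test_that("create_individual samples within bounds, deterministically", {
  spec <- param_spec(w = list(shape = 3, low = 0, high = 1))
  set.seed(42); a <- create_individual(spec)
  set.seed(42); b <- create_individual(spec)
  expect_identical(a, b)
  expect_true(all(a$values$w >= 0 & a$values$w <= 1))
})

test_that("mixed continuous/integer blocks honor shapes and kinds", {
  spec <- param_spec(w = list(shape = 250, low = -20, high = 20),
                     d = list(shape = 250, low = 1, high = 6, kind = "integer"))
  set.seed(1)
  ind <- create_individual(spec)
  expect_length(ind$values$w, 250)
  expect_length(ind$values$d, 250)
  expect_true(all(ind$values$d == round(ind$values$d)))
  expect_true(all(ind$values$d >= 1 & ind$values$d <= 6))
  expect_equal(spec_dimension(spec), 500)
})

test_that("the uniform sampler is calibrated", {
  spec <- param_spec(x = list(low = 0, high = 1))
  set.seed(7)
  draws <- replicate(10000, create_individual(spec)$values$x)
  expect_gte(min(draws), 0)
  expect_lte(max(draws), 1)
  expect_equal(mean(draws), 0.5, tolerance = 0.02 / 0.5)
})

test_that("empty or malformed specs are rejected", {
  expect_error(param_spec(), "empty")
  expect_error(param_spec(a = list(low = 1, high = 1)), "low < high")
  expect_error(param_spec(a = list(low = 0, high = 1),
                          a = list(low = 0, high = 1)), "unique")
})

test_that("apply_bounds clamps, rounds integers, and is idempotent", {
  spec <- param_spec(w = list(low = -20, high = 20),
                     d = list(low = 1, high = 5, kind = "integer"))
  ind <- new_individual(list(w = 25, d = 6.7))
  out <- apply_bounds(ind, spec)
  expect_equal(out$values$w, 20)
  expect_equal(out$values$d, 5)
  expect_identical(apply_bounds(out, spec)$values, out$values)

  inr <- new_individual(list(w = 3, d = 2))
  expect_identical(apply_bounds(inr, spec)$values, list(w = 3, d = 2))

  bad <- new_individual(list(q = 1, d = 2))
  expect_error(apply_bounds(bad, spec), "do not match")
})

test_that("flatten/unflatten round-trips in stable block order", {
  spec <- param_spec(a = list(shape = 2, low = 0, high = 1),
                     b = list(shape = 3, low = -1, high = 1))
  set.seed(3)
  ind <- create_individual(spec, id = 4L, generation = 2L)
  flat <- flatten_individual(ind, spec)
  expect_length(flat, 5)
  back <- unflatten_individual(unname(flat), spec, id = 4L, generation = 2L)
  expect_equal(back$values, ind$values)

  pop <- lapply(1:3, function(i) create_individual(spec, id = i))
  m <- population_matrix(pop, spec)
  expect_equal(dim(m), c(3, 5))
  expect_equal(matrix_population(m, spec)[[2]]$values, pop[[2]]$values)
})
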