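make_traj <- function(n_gen = 3L, n_pop = 4L, seed = 1L) {
  spec <- param_spec(x = list(shape = 2, low = -1, high = 1))
  traj <- trajectory(config = list(note = "fixture"), seed = seed)
  set.seed(seed)
  for (g in seq_len(n_gen)) {
    inds <- lapply(seq_len(n_pop) - 1L, function(i) {
      create_individual(spec, id = i, generation = g - 1L)
    })
    recs <- lapply(inds, function(ind) {
      fv <- -sum(ind$values$x^2)
      fitness_record(ind$id, fv, fv, seed = derive_seed(seed, g, ind$id))
    })
    traj <- trajectory_append(traj, inds, recs)
  }
  traj
}

test_that("a trajectory store round-trips exactly", {
  traj <- make_traj()
  path <- withr::local_tempfile(fileext = ".json")
  persist_trajectory(traj, path)
  back <- load_trajectory(path)
  expect_equal(back, traj)
})

test_that("an empty trajectory round-trips", {
  traj <- trajectory(config = list(a = 1), seed = 9L)
  path <- withr::local_tempfile(fileext = ".json")
  persist_trajectory(traj, path)
  expect_equal(load_trajectory(path), traj)
})

test_that("non-finite fitness values survive persistence", {
  traj <- trajectory(seed = 1L)
  ind <- new_individual(list(x = 0.5))
  rec <- fitness_record(0L, -Inf, -Inf, failed = TRUE)
  traj <- trajectory_append(traj, list(ind), list(rec))
  path <- withr::local_tempfile(fileext = ".json")
  persist_trajectory(traj, path)
  expect_identical(load_trajectory(path)$generations[[1]]$records[[1]]$scalar_fitness,
                   -Inf)
})

test_that("the CSV export has one row per (generation, individual)", {
  traj <- make_traj(n_gen = 3L, n_pop = 4L)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- export_trajectory_csv(traj, path)
  expect_equal(nrow(df), 12)
  on_disk <- read.csv(path)
  expect_equal(nrow(on_disk), 12)
  expect_true(all(c("generation", "individual_id", "scalar_fitness") %in%
                  names(on_disk)))
})

test_that("a corrupt store reports the failing generation", {
  traj <- make_traj(n_gen = 2L)
  path <- withr::local_tempfile(fileext = ".json")
  persist_trajectory(traj, path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  doc$generations[[2]]$records <- "garbage"
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null")
  expect_error(load_trajectory(path), "generation 2")
})

test_that("trajectory_best and the fitness history agree", {
  traj <- make_traj(n_gen = 3L)
  h <- trajectory_fitness_history(traj)
  expect_length(h, 3)
  expect_equal(trajectory_best(traj)$fitness, max(h))
})
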