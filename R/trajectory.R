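#' Trajectory: the persisted history of a two-loop run
#'
#' A trajectory records, per generation, every individual and its fitness
#' record (fitness vector, scalarized fitness, evaluation seed), plus a
#' snapshot of the run configuration and the experiment seed. Append-only.
#'
#' @param config arbitrary configuration snapshot (list).
#' @param seed experiment seed (integer).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(config = list(), seed = NA_integer_) {
  structure(list(config = config, seed = seed, generations = list()),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- length(x$generations)
  cat(sprintf("<trajectory> %d generation(s), seed %s\n", n, format(x$seed)))
  if (n > 0L) {
    bf <- trajectory_best(x)
    cat(sprintf("  population %d, best scalar fitness %.6g (generation %d)\n",
                length(x$generations[[1L]]$individuals), bf$fitness, bf$generation))
  }
  invisible(x)
}

#' Append one evaluated generation to a trajectory
#'
#' @param traj a [trajectory()].
#' @param individuals list of individuals as evaluated.
#' @param records list of fitness records from [evaluate_generation()].
#' @return The extended trajectory.
#' @export
trajectory_append <- function(traj, individuals, records) {
  stopifnot(inherits(traj, "trajectory"), length(individuals) == length(records))
  traj$generations[[length(traj$generations) + 1L]] <-
    list(individuals = individuals, records = records)
  traj
}

#' Best individual and fitness seen anywhere in a trajectory
#' @param traj a [trajectory()].
#' @return List with `individual`, `fitness`, `generation`.
#' @export
trajectory_best <- function(traj) {
  best <- list(individual = NULL, fitness = -Inf, generation = NA_integer_)
  for (g in seq_along(traj$generations)) {
    gen <- traj$generations[[g]]
    fs <- vapply(gen$records, `[[`, numeric(1), "scalar_fitness")
    i <- which.max(fs)
    if (length(i) == 1L && fs[i] > best$fitness) {
      best <- list(individual = gen$individuals[[i]], fitness = fs[i], generation = g)
    }
  }
  best
}

#' Best individual of the final generation
#'
#' The end product of an evolutionary run: the highest-fitness individual
#' of the last recorded generation. For noisy single-episode fitness this
#' is usually a more robust champion than [trajectory_best()], which can
#' return a lucky early transient.
#'
#' @param traj a [trajectory()].
#' @return List with `individual`, `fitness`, `generation`.
#' @export
trajectory_final_best <- function(traj) {
  n <- length(traj$generations)
  if (n == 0L) return(list(individual = NULL, fitness = -Inf,
                           generation = NA_integer_))
  gen <- traj$generations[[n]]
  fs <- vapply(gen$records, `[[`, numeric(1), "scalar_fitness")
  i <- which.max(fs)
  list(individual = gen$individuals[[i]], fitness = fs[i], generation = n)
}

#' Per-generation best scalar fitness
#' @param traj a [trajectory()].
#' @return Numeric vector, one entry per generation.
#' @export
trajectory_fitness_history <- function(traj) {
  vapply(traj$generations, function(gen) {
    max(vapply(gen$records, `[[`, numeric(1), "scalar_fitness"))
  }, numeric(1))
}

# -Inf/Inf/NA are not representable as bare JSON numbers; encode as strings.
.num_encode <- function(x) {
  x <- as.numeric(x)
  out <- as.list(x)
  bad <- !is.finite(x)
  out[bad] <- as.character(x[bad])
  out
}

.num_decode <- function(x) vapply(x, function(v) as.numeric(v), numeric(1))

#' Persist a trajectory to disk / load it back
#'
#' The store is a self-describing JSON document: configuration snapshot,
#' seed, and per-generation tables of individuals and fitness records.
#' `load_trajectory()` returns an object equal to the one saved.
#'
#' @param traj a [trajectory()].
#' @param path file path to write to / read from.
#' @return `persist_trajectory`: `path`, invisibly. `load_trajectory`: the
#'   reconstructed trajectory.
#' @export
persist_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  doc <- list(
    format = "metaloop-trajectory",
    version = 1L,
    seed = traj$seed,
    config = traj$config,
    generations = lapply(traj$generations, function(gen) {
      list(
        individuals = lapply(gen$individuals, function(ind) {
          list(id = ind$id, generation = ind$generation,
               values = lapply(ind$values, .num_encode))
        }),
        records = lapply(gen$records, function(r) {
          list(individual_id = r$individual_id,
               fitness_vector = .num_encode(r$fitness_vector),
               scalar_fitness = .num_encode(r$scalar_fitness)[[1L]],
               seed = if (is.na(r$seed)) NULL else r$seed,
               failed = isTRUE(r$failed))
        })
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname persist_trajectory
#' @export
load_trajectory <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "metaloop-trajectory")) {
    stop("not a metaloop trajectory store: ", path, call. = FALSE)
  }
  traj <- trajectory(config = doc$config,
                     seed = if (is.null(doc$seed)) NA_integer_ else as.integer(doc$seed))
  for (g in seq_along(doc$generations)) {
    gen <- tryCatch({
      gd <- doc$generations[[g]]
      individuals <- lapply(gd$individuals, function(ind) {
        new_individual(lapply(ind$values, .num_decode),
                       id = ind$id, generation = ind$generation)
      })
      records <- lapply(gd$records, function(r) {
        fitness_record(individual_id = as.integer(r$individual_id),
                       fitness_vector = .num_decode(r$fitness_vector),
                       scalar_fitness = as.numeric(r$scalar_fitness),
                       seed = if (is.null(r$seed)) NA_integer_
                              else as.integer(r$seed),
                       failed = isTRUE(r$failed))
      })
      list(individuals = individuals, records = records)
    }, error = function(e) {
      stop(sprintf("corrupt trajectory store '%s' at generation %d: %s",
                   path, g, conditionMessage(e)), call. = FALSE)
    })
    traj$generations[[g]] <- gen
  }
  traj
}

#' Export a trajectory as a flat per-generation CSV table
#'
#' One row per (generation, individual) with flattened parameter columns and
#' fitness columns, suitable for external analysis tools.
#'
#' @param traj a [trajectory()].
#' @param path CSV file path.
#' @return The exported data frame, invisibly.
#' @export
export_trajectory_csv <- function(traj, path) {
  rows <- list()
  for (g in seq_along(traj$generations)) {
    gen <- traj$generations[[g]]
    for (i in seq_along(gen$individuals)) {
      ind <- gen$individuals[[i]]
      rec <- gen$records[[i]]
      flat <- unlist(ind$values, use.names = TRUE)
      row <- c(list(generation = g - 1L, individual_id = rec$individual_id),
               as.list(flat),
               setNames(as.list(rec$fitness_vector),
                        paste0("fitness_", seq_along(rec$fitness_vector))),
               list(scalar_fitness = rec$scalar_fitness))
      rows[[length(rows) + 1L]] <- as.data.frame(row, check.names = TRUE)
    }
  }
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
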