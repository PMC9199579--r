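#' Evaluate an individual through an external command via CSV exchange
#'
#' Couples the framework to optimizees written in any language: the
#' individual's parameters are written to `params.csv` in the working
#' directory (columns `name,index,value`, one row per scalar, UTF-8,
#' '.'-decimal), the command is run as a blocking subordinate process, and
#' the resulting `fitness.csv` (a single row of reals) is read back.
#'
#' @param command shell command to execute (run with `sh -c` in `workdir`).
#' @param ind the individual to evaluate.
#' @param workdir working directory for the exchange files.
#' @return Numeric fitness vector read from `fitness.csv`.
#' @export
run_external <- function(command, ind, workdir = tempfile("metaloop_ext_")) {
  stopifnot(inherits(ind, "individual"))
  if (!dir.exists(workdir)) dir.create(workdir, recursive = TRUE)
  rows <- do.call(rbind, lapply(names(ind$values), function(nm) {
    v <- ind$values[[nm]]
    data.frame(name = nm, index = seq_along(v) - 1L, value = v)
  }))
  params_path <- file.path(workdir, "params.csv")
  fitness_path <- file.path(workdir, "fitness.csv")
  if (file.exists(fitness_path)) unlink(fitness_path)
  write.csv(rows, params_path, row.names = FALSE, quote = FALSE)

  stderr_path <- file.path(workdir, "stderr.log")
  wrapped <- sprintf("cd %s && { %s ; }", shQuote(workdir), command)
  status <- system2("sh", c("-c", shQuote(wrapped)),
                    stdout = FALSE, stderr = stderr_path, wait = TRUE)
  captured <- if (file.exists(stderr_path)) {
    paste(readLines(stderr_path, warn = FALSE), collapse = "\n")
  } else ""
  if (!identical(status, 0L)) {
    stop(sprintf("external optimizee exited with status %d: %s", status, captured),
         call. = FALSE)
  }
  if (!file.exists(fitness_path)) {
    stop("external optimizee produced no fitness.csv: ", captured, call. = FALSE)
  }
  fv <- tryCatch({
    line <- readLines(fitness_path, warn = FALSE)[1L]
    as.numeric(strsplit(trimws(line), ",")[[1L]])
  }, error = function(e) NULL)
  if (is.null(fv) || length(fv) == 0L || anyNA(fv)) {
    stop("unparsable fitness.csv from external optimizee: ", captured, call. = FALSE)
  }
  fv
}
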