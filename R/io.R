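#' Write states as multi-frame XYZ
#'
#' Standard XYZ trajectory text format: per frame an atom-count line, a
#' comment line carrying the time and the efficiency, then one `A x y z vx
#' vy vz` line per agent (velocities as extra columns, a common XYZ
#' extension).
#'
#' @param states a [swarm_state()] or list of them.
#' @param file output path.
#' @param params a [model_params()] (for the efficiency in the comment
#'   line); optional.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(states, file, params = NULL) {
  if (inherits(states, "swarm_state")) states <- list(states)
  con <- file(file, "w")
  on.exit(close(con))
  for (st in states) {
    N <- nrow(st$positions)
    e <- if (is.null(params)) NA_real_ else efficiency(st, params)
    writeLines(c(as.character(N),
                 sprintf("t= %.10g E= %.10g", st$t, e)), con)
    writeLines(sprintf("A %.10g %.10g %.10g %.10g %.10g %.10g",
                       st$positions[, 1], st$positions[, 2],
                       st$positions[, 3], st$velocities[, 1],
                       st$velocities[, 2], st$velocities[, 3]), con)
  }
  invisible(file)
}

#' Read a multi-frame XYZ trajectory
#'
#' Inverse of [write_xyz()]; positions and velocities are restored so a
#' run can be resumed from any frame.
#'
#' @param file path written by [write_xyz()].
#' @return A list of [swarm_state()] objects.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  out <- list()
  k <- 1L
  while (k <= length(lines)) {
    N <- as.integer(lines[k])
    tok <- strsplit(trimws(lines[k + 1L]), "\\s+")[[1]]
    t <- as.numeric(tok[2])
    body <- lines[(k + 2L):(k + 1L + N)]
    m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), function(x) {
      as.numeric(x[2:7])
    }))
    out[[length(out) + 1L]] <- swarm_state(m[, 1:3, drop = FALSE],
                                           m[, 4:6, drop = FALSE], t = t)
    k <- k + 2L + N
  }
  out
}

#' Write a trajectory as flat CSV
#'
#' One row per agent and frame: `t, agent, x, y, z, vx, vy, vz`.
#'
#' @param states a [swarm_state()] or list of them.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_traj_csv <- function(states, file) {
  if (inherits(states, "swarm_state")) states <- list(states)
  rows <- do.call(rbind, lapply(states, function(st) {
    data.frame(t = st$t, agent = seq_len(nrow(st$positions)),
               x = st$positions[, 1], y = st$positions[, 2],
               z = st$positions[, 3], vx = st$velocities[, 1],
               vy = st$velocities[, 2], vz = st$velocities[, 3])
  }))
  write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Read a CSV trajectory
#'
#' @param file path written by [write_traj_csv()].
#' @return A list of [swarm_state()] objects, one per distinct time.
#' @export
read_traj_csv <- function(file) {
  d <- read.csv(file)
  lapply(split(d, d$t), function(f) {
    f <- f[order(f$agent), ]
    swarm_state(as.matrix(f[, c("x", "y", "z")]),
                as.matrix(f[, c("vx", "vy", "vz")]), t = f$t[1])
  })
}

#' Write an efficiency series as CSV
#'
#' @param series data.frame with `t` and `E` (as in `run_sim()$series`).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_series_csv <- function(series, file) {
  write.csv(series[, c("t", "E")], file, row.names = FALSE)
  invisible(file)
}

#' Write run metadata as a JSON sidecar
#'
#' Records everything needed to reproduce a run: the full parameter set,
#' the seed and the package version.
#'
#' @param params a [model_params()] object.
#' @param seed the integer seed used.
#' @param file output path.
#' @param extra optional named list merged into the record.
#' @return `file`, invisibly.
#' @export
write_run_meta <- function(params, seed, file, extra = NULL) {
  meta <- c(list(params = unclass(params), seed = seed,
                 package = "flock3d",
                 version = as.character(utils::packageVersion("flock3d"))),
            extra)
  jsonlite::write_json(meta, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Write an ensemble histogram as CSV (plus JSON metadata)
#'
#' @param summary an [ensemble_histogram()] result.
#' @param file CSV output path; a `.json` sidecar with the run count, bin
#'   width and time ratio is written next to it.
#' @return `file`, invisibly.
#' @export
write_ensemble_csv <- function(summary, file) {
  stopifnot(inherits(summary, "ensemble_summary"))
  write.csv(summary$histogram, file, row.names = FALSE)
  jsonlite::write_json(
    list(n_runs = summary$n_runs, bin_width = summary$bin_width,
         time_ratio = summary$time_ratio),
    paste0(sub("\\.csv$", "", file), ".json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
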