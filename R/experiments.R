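#' Experiment specification
#'
#' Reproducible description of a macroscopic experiment: which protocol to
#' run, with which parameters, how many independent runs, for how long, and
#' under which seeds. Re-running the same spec reproduces every noiseless
#' output exactly and every stochastic output run-for-run (same seeds give
#' the same trajectories).
#'
#' @param kind one of `"order_transition"`, `"noise_hysteresis"`,
#'   `"delay_sweep"`, `"pair_scan"`.
#' @param params a [model_params()] object (per-protocol fields such as
#'   `xi` or `t_d` are overridden by the grids below).
#' @param runs independent runs per condition (`>= 1`).
#' @param horizon simulated duration per run (s), a multiple of `dt`.
#' @param record_every recording cadence (s).
#' @param seeds integer seeds, one per run; must be distinct. Default
#'   `seq_len(runs)`.
#' @param xi_grid noise amplitudes for `noise_hysteresis`.
#' @param delay_grid interaction delays (s) for `delay_sweep`; each must be
#'   a multiple of `dt`.
#' @param equilibration equilibration interval (s) for ordered starts.
#' @param tail_fraction fraction of the horizon (from the end) averaged to
#'   report the "tail" efficiency of a run.
#' @param step_budget warn when the total step count across all runs of
#'   the spec exceeds this (a desk-scale resource guard).
#' @return An object of class `experiment_spec`.
#' @examples
#' experiment_spec("order_transition", desk_params(), runs = 2, horizon = 10)
#' @export
experiment_spec <- function(kind = c("order_transition", "noise_hysteresis",
                                     "delay_sweep", "pair_scan"),
                            params = model_params(), runs = 5,
                            horizon = 1e4, record_every = NULL,
                            seeds = NULL, xi_grid = NULL, delay_grid = NULL,
                            equilibration = NULL, tail_fraction = 0.1,
                            step_budget = 5e8) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "flock_params"), runs >= 1, horizon > 0,
            tail_fraction > 0, tail_fraction <= 1)
  if (is.null(seeds)) seeds <- seq_len(runs)
  seeds <- as.integer(seeds)
  stopifnot(length(seeds) == runs, !anyDuplicated(seeds))
  if (is.null(record_every)) {
    record_every <- max(params$dt, horizon / 1000)
    record_every <- round(record_every / params$dt) * params$dt
  }
  if (is.null(equilibration)) equilibration <- horizon / 10
  n_cond <- max(1, length(xi_grid)) * max(1, length(delay_grid))
  total_steps <- runs * n_cond * (horizon / params$dt) *
    (if (kind %in% c("noise_hysteresis", "delay_sweep")) 2 else 1)
  if (total_steps > step_budget) {
    warning(sprintf(
      "spec totals ~%.2g integration steps (budget %.2g); expect a long run",
      total_steps, step_budget))
  }
  structure(list(kind = kind, params = params, runs = runs,
                 horizon = horizon, record_every = record_every,
                 seeds = seeds, xi_grid = xi_grid, delay_grid = delay_grid,
                 equilibration = equilibration,
                 tail_fraction = tail_fraction),
            class = "experiment_spec")
}

# signature string stored with every output row for provenance
param_signature <- function(params) {
  paste0("N", params$N, "_L", signif(params$L, 6), "_v0", params$v0,
         "_tau", params$tau, "_c", params$c, "_R", params$R,
         "_xi", params$xi, "_dt", params$dt, "_td", params$t_d,
         "_", params$noise_scaling)
}

tail_mean_E <- function(series, fraction) {
  t1 <- max(series$t)
  t0 <- t1 - fraction * (t1 - min(series$t))
  mean(series$E[series$t >= t0])
}

run_one <- function(params, horizon, record_every, seed, start,
                    equilibration) {
  st <- if (start == "disordered") {
    init_disordered(params, seed = seed)
  } else {
    init_ordered(params, seed = seed, equilibration = equilibration)
  }
  run_sim(st, params, T = horizon, record_every = record_every)
}

#' Ordering of a disordered swarm
#'
#' Independent disordered-start runs of the noiseless (or noisy, per
#' `spec$params`) model, with the per-run efficiency series, the ensemble
#' mean curve, the Binder cumulant over ratio-spaced times, the ensemble
#' histogram and the per-run transition times. A failed run is recorded and
#' the ensemble continues.
#'
#' @param spec an [experiment_spec()] of kind `"order_transition"`.
#' @param threshold,dwell passed to [transition_time()].
#' @return A list of class `order_transition`: `series` (long data.frame
#'   `run`, `seed`, `t`, `E`), `mean_E` (`t`, `E`), `summary` (one row per
#'   run with seed, tail E and transition time), `histogram`
#'   (an [ensemble_histogram()]), `failures`, `spec`.
#' @examples
#' \donttest{
#' sp <- experiment_spec("order_transition", desk_params(), runs = 2,
#'                       horizon = 50)
#' ot <- order_transition(sp)
#' }
#' @export
order_transition <- function(spec, threshold = 0.8, dwell = NULL) {
  stopifnot(inherits(spec, "experiment_spec"))
  sig <- param_signature(spec$params)
  runs <- list(); fails <- list(); rows <- list()
  for (k in seq_len(spec$runs)) {
    seed <- spec$seeds[k]
    res <- tryCatch(
      run_one(spec$params, spec$horizon, spec$record_every, seed,
              "disordered", spec$equilibration),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1]] <- data.frame(run = k, seed = seed,
                                               message = conditionMessage(res))
      next
    }
    runs[[length(runs) + 1]] <- res$series
    rows[[length(rows) + 1]] <- data.frame(
      run = k, seed = seed, signature = sig,
      tail_E = tail_mean_E(res$series, spec$tail_fraction),
      transition_time = transition_time(res$series, threshold, dwell))
  }
  if (length(runs) == 0) stop("all runs failed")
  long <- do.call(rbind, lapply(seq_along(runs), function(k) {
    cbind(run = k, seed = rows[[k]]$seed, runs[[k]])
  }))
  mean_E <- data.frame(
    t = runs[[1]]$t,
    E = rowMeans(vapply(runs, function(r) r$E, numeric(nrow(runs[[1]])))))
  structure(list(series = long, mean_E = mean_E,
                 summary = do.call(rbind, rows),
                 histogram = ensemble_histogram(runs),
                 failures = if (length(fails)) do.call(rbind, fails) else NULL,
                 spec = spec),
            class = "order_transition")
}

#' @export
print.order_transition <- function(x, ...) {
  cat(sprintf("order_transition: %d runs, horizon %g s; tail E: %s\n",
              nrow(x$summary), x$spec$horizon,
              paste(sprintf("%.3f", x$summary$tail_E), collapse = " ")))
  invisible(x)
}

#' Noise hysteresis experiment
#'
#' For each noise amplitude on the grid and each start mode (disordered;
#' ordered after equilibration) the swarm is run over the horizon and the
#' time-averaged tail efficiency is reported per run and per condition. A
#' hysteresis window is flagged at amplitudes where the ordered start stays
#' ordered (mean tail E above `ordered_above`) while the disordered start
#' stays disordered (below `disordered_below`) — the signature of a
#' discontinuous transition.
#'
#' @param spec an [experiment_spec()] with a nonempty `xi_grid`.
#' @param ordered_above,disordered_below classification thresholds on the
#'   tail efficiency (the gap in between is undecided).
#' @return A list of class `noise_hysteresis`: `runs` (per-run rows),
#'   `summary` (per `xi` and start mode), `hysteresis` (per `xi`: logical
#'   flag), `failures`, `spec`.
#' @examples
#' \donttest{
#' sp <- experiment_spec("noise_hysteresis", desk_params(), runs = 2,
#'                       horizon = 50, xi_grid = c(0, 50))
#' nh <- noise_hysteresis(sp)
#' }
#' @export
noise_hysteresis <- function(spec, ordered_above = 0.8,
                             disordered_below = 0.3) {
  stopifnot(inherits(spec, "experiment_spec"), length(spec$xi_grid) >= 1)
  rows <- list(); fails <- list()
  for (xi in spec$xi_grid) {
    p <- spec$params; p$xi <- xi
    for (start in c("disordered", "ordered")) {
      for (k in seq_len(spec$runs)) {
        seed <- spec$seeds[k]
        res <- tryCatch(
          run_one(p, spec$horizon, spec$record_every, seed, start,
                  spec$equilibration),
          error = function(e) e)
        if (inherits(res, "error")) {
          fails[[length(fails) + 1]] <- data.frame(
            xi = xi, start = start, run = k, seed = seed,
            message = conditionMessage(res))
          next
        }
        rows[[length(rows) + 1]] <- data.frame(
          xi = xi, start = start, run = k, seed = seed,
          signature = param_signature(p),
          tail_E = tail_mean_E(res$series, spec$tail_fraction))
      }
    }
  }
  runs <- do.call(rbind, rows)
  summary <- aggregate(tail_E ~ xi + start, data = runs, FUN = mean)
  wide <- merge(summary[summary$start == "ordered", c("xi", "tail_E")],
                summary[summary$start == "disordered", c("xi", "tail_E")],
                by = "xi", suffixes = c("_ordered", "_disordered"))
  wide$hysteresis <- wide$tail_E_ordered > ordered_above &
    wide$tail_E_disordered < disordered_below
  structure(list(runs = runs, summary = summary, hysteresis = wide,
                 failures = if (length(fails)) do.call(rbind, fails) else NULL,
                 spec = spec),
            class = "noise_hysteresis")
}

#' @export
print.noise_hysteresis <- function(x, ...) {
  cat("noise_hysteresis:\n")
  print(x$hysteresis, row.names = FALSE)
  invisible(x)
}

#' Interaction-delay sweep
#'
#' Runs the model at each interaction delay on the grid from both start
#' modes. Disordered starts report the ordering rate (the transition time
#' to sustained high efficiency); ordered starts report the tail
#' efficiency, probing whether delay destroys an established flock. With
#' `t_d = 0` the protocol reproduces [order_transition()] behaviour
#' exactly.
#'
#' @param spec an [experiment_spec()] with a nonempty `delay_grid` (s, each
#'   a multiple of `dt`).
#' @param threshold,dwell passed to [transition_time()].
#' @return A list of class `delay_sweep`: `runs` (per-run rows with
#'   `t_d`, start mode, tail E and transition time), `summary` (means per
#'   `t_d` and mode), `series` (long per-run efficiency series),
#'   `failures`, `spec`.
#' @examples
#' \donttest{
#' sp <- experiment_spec("delay_sweep", desk_params(), runs = 2,
#'                       horizon = 50, delay_grid = c(0, 0.01))
#' ds <- delay_sweep(sp)
#' }
#' @export
delay_sweep <- function(spec, threshold = 0.8, dwell = NULL) {
  stopifnot(inherits(spec, "experiment_spec"), length(spec$delay_grid) >= 1)
  rows <- list(); fails <- list(); longs <- list()
  for (td in spec$delay_grid) {
    p <- spec$params
    p$t_d <- td
    k_steps <- td / p$dt
    if (abs(k_steps - round(k_steps)) > 1e-9 * max(1, k_steps)) {
      stop("every delay on the grid must be a multiple of dt")
    }
    p$delay_steps <- as.integer(round(k_steps))
    for (start in c("disordered", "ordered")) {
      for (k in seq_len(spec$runs)) {
        seed <- spec$seeds[k]
        res <- tryCatch(
          run_one(p, spec$horizon, spec$record_every, seed, start,
                  spec$equilibration),
          error = function(e) e)
        if (inherits(res, "error")) {
          fails[[length(fails) + 1]] <- data.frame(
            t_d = td, start = start, run = k, seed = seed,
            message = conditionMessage(res))
          next
        }
        rows[[length(rows) + 1]] <- data.frame(
          t_d = td, start = start, run = k, seed = seed,
          signature = param_signature(p),
          tail_E = tail_mean_E(res$series, spec$tail_fraction),
          transition_time = transition_time(res$series, threshold, dwell))
        longs[[length(longs) + 1]] <- cbind(t_d = td, start = start,
                                            run = k, res$series)
      }
    }
  }
  runs <- do.call(rbind, rows)
  summary <- aggregate(cbind(tail_E, transition_time) ~ t_d + start,
                       data = runs, FUN = function(z) mean(z),
                       na.action = stats::na.pass)
  structure(list(runs = runs, summary = summary,
                 series = do.call(rbind, longs),
                 failures = if (length(fails)) do.call(rbind, fails) else NULL,
                 spec = spec),
            class = "delay_sweep")
}

#' @export
print.delay_sweep <- function(x, ...) {
  cat("delay_sweep:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
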