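#' Force history for delayed interactions
#'
#' Ring buffer of past force evaluations enabling time-lagged dynamics: with
#' delay `t_d = k * dt`, a lookup at step `s` returns the record stored at
#' step `s - k`. Before the buffer holds `k` records (warm-up, including the
#' start of every run) the oldest available record is returned, which avoids
#' a discontinuous force onset.
#'
#' Used by the R-level [midpoint_step()]; the compiled [run_sim()] loop
#' maintains its own equivalent buffers.
#'
#' @param delay_steps integer `k >= 0` with `t_d = k * dt`.
#' @return An object of class `force_history`.
#' @examples
#' h <- force_history(2)
#' @export
force_history <- function(delay_steps) {
  stopifnot(delay_steps >= 0, delay_steps == floor(delay_steps))
  structure(list(delay_steps = as.integer(delay_steps),
                 full = list(), half = list(), step = 0L),
            class = "force_history")
}

# append a record and return the (clamped) one delay_steps back;
# keeps at most delay_steps + 1 records
ring_push <- function(lst, x, k) {
  lst[[length(lst) + 1L]] <- x
  if (length(lst) > k + 1L) lst <- lst[-1L]
  lst
}
ring_get <- function(lst, k) lst[[max(1L, length(lst) - k)]]

#' Single forward-Euler step
#'
#' Advances a swarm state by one explicit Euler update: velocities gain
#' `F/m * dt` (plus a noise impulse over `dt` when `xi > 0`), positions
#' advance with the pre-update velocities and are wrapped into the box.
#' First-order accurate; adequate for two-body encounters, while the
#' many-agent production runs use [midpoint_step()] / [run_sim()].
#'
#' @param state a [swarm_state()].
#' @param params a [model_params()] object.
#' @return The advanced `swarm_state` at `t + dt`.
#' @examples
#' p <- model_params(N = 1)
#' s <- swarm_state(matrix(1, 1, 3), matrix(c(10, 0, 0), 1, 3), L = p$L)
#' euler_step(s, p)
#' @export
euler_step <- function(state, params) {
  check_state(state, params)
  f <- net_forces(state, neighbor_pairs(state, params), params)
  if (!all(is.finite(f))) stop("non-finite force (agent overlap?)")
  v <- state$velocities + f * (params$dt / params$mass)
  if (params$xi > 0) {
    v <- v + noise_impulse(params$xi, params$dt, params$mass, params$N,
                           params$noise_scaling)
  }
  r <- wrap_position(state$positions + state$velocities * params$dt, params$L)
  swarm_state(r, v, t = state$t + params$dt, L = params$L)
}

#' Single explicit midpoint step
#'
#' One step of the production integrator. Forces `F1` are evaluated at the
#' current state; a half-step state at `t + dt/2` is formed with `F1` (plus
#' a noise impulse over `dt/2` when `xi > 0`); forces `F2` are evaluated
#' there; then `v <- v + F2/m * dt` (plus a noise impulse over `dt`) and
#' positions advance with the half-step velocities. With a delay
#' (`t_d > 0`), `F1` and `F2` are replaced by the recorded forces from
#' `t - t_d` (clamped during warm-up) while freshly evaluated forces are
#' always appended to the history; noise is never delayed.
#'
#' This R implementation mirrors the compiled loop in [run_sim()] and exists
#' for transparency and cross-checking; use [run_sim()] for long runs.
#'
#' @param state a [swarm_state()].
#' @param params a [model_params()] object.
#' @param history a [force_history()], required when `params$t_d > 0`. When
#'   supplied, the updated history is attached to the returned state as
#'   attribute `"force_history"`.
#' @return The advanced `swarm_state` at `t + dt`.
#' @examples
#' p <- model_params(N = 1)
#' s <- swarm_state(matrix(1, 1, 3), matrix(c(10, 0, 0), 1, 3), L = p$L)
#' midpoint_step(s, p)
#' @export
midpoint_step <- function(state, params, history = NULL) {
  check_state(state, params)
  if (params$delay_steps > 0 && is.null(history)) {
    stop("t_d > 0 requires an initialized force_history")
  }
  dt <- params$dt
  f1 <- net_forces(state, neighbor_pairs(state, params), params)
  if (!all(is.finite(f1))) stop("non-finite force (agent overlap?)")
  f1_use <- f1
  if (!is.null(history)) {
    history$step <- history$step + 1L
    history$full <- ring_push(history$full, f1, history$delay_steps)
    f1_use <- ring_get(history$full, history$delay_steps)
  }
  half_state <- function(f_used) {
    vh <- state$velocities + f_used * (dt / 2 / params$mass)
    if (params$xi > 0) {
      vh <- vh + noise_impulse(params$xi, dt / 2, params$mass, params$N,
                               params$noise_scaling)
    }
    ph <- state$positions + state$velocities * (dt / 2)
    list(
      vh = vh,
      st = swarm_state(wrap_position(ph, params$L), vh,
                       t = state$t + dt / 2, L = params$L))
  }
  hs <- half_state(f1_use)
  f2 <- net_forces(hs$st, neighbor_pairs(hs$st, params), params)
  if (!all(is.finite(f2))) stop("non-finite force (agent overlap?)")
  f2_use <- f2
  if (!is.null(history)) {
    history$half <- ring_push(history$half, f2, history$delay_steps)
    f2_use <- ring_get(history$half, history$delay_steps)
  }
  v <- state$velocities + f2_use * (dt / params$mass)
  if (params$xi > 0) {
    v <- v + noise_impulse(params$xi, dt, params$mass, params$N,
                           params$noise_scaling)
  }
  r <- wrap_position(state$positions + hs$vh * dt, params$L)
  out <- swarm_state(r, v, t = state$t + dt, L = params$L)
  if (!is.null(history)) attr(out, "force_history") <- history
  out
}

#' Run the simulation
#'
#' Advances a swarm by repeated midpoint steps in the compiled engine,
#' recording the polar order parameter (efficiency) at a fixed cadence and
#' optionally full trajectory frames. The run is fully determined by `seed`
#' (identical seeds give identical trajectories; with `xi = 0` and fixed
#' delay the run is deterministic outright).
#'
#' @param state initial [swarm_state()].
#' @param params a [model_params()] object; `params$t_d` (a multiple of
#'   `dt`) activates delayed forces.
#' @param T duration to simulate (s); must be a multiple of `dt`.
#' @param record_every recording interval (s); must be a multiple of `dt`.
#' @param seed optional integer seed applied before the run.
#' @param use_history force the delay machinery on even when `t_d = 0`
#'   (used to verify zero-delay equivalence); default `params$t_d > 0`.
#' @param record_trajectory keep position/velocity frames at each recording
#'   time (memory grows accordingly).
#' @return A list of class `flock_run`: `series` (data.frame `t`, `E`),
#'   `state` (final `swarm_state`), `n_rebuild`, `n_clamped` (delay warm-up
#'   lookups), and `trajectory` (list of `swarm_state`, if requested).
#' @examples
#' p <- desk_params()
#' s <- init_disordered(p, seed = 1)
#' r <- run_sim(s, p, T = 0.01, record_every = 0.01)
#' r$series
#' @export
run_sim <- function(state, params, T, record_every = 100 * params$dt,
                    seed = NULL, use_history = params$delay_steps > 0,
                    record_trajectory = FALSE) {
  check_state(state, params)
  stopifnot(T > 0)
  n_steps <- round(T / params$dt)
  if (abs(n_steps * params$dt - T) > 1e-9 * max(1, T)) {
    stop("T must be a multiple of dt")
  }
  rec <- round(record_every / params$dt)
  if (rec < 1 || abs(rec * params$dt - record_every) > 1e-9 * max(1, record_every)) {
    stop("record_every must be a positive multiple of dt")
  }
  if (!is.null(seed)) set.seed(seed)
  res <- run_sim_cpp(state$positions, state$velocities,
                     params$L, params$v0, params$tau, params$mass, params$c,
                     params$R, params$xi, params$dt,
                     as.integer(n_steps), as.integer(rec),
                     params$delay_steps, use_history,
                     params$noise_scaling == "sqrt",
                     params$skin, record_trajectory)
  series <- data.frame(t = state$t + res$times, E = res$efficiency)
  traj <- NULL
  if (record_trajectory) {
    traj <- lapply(seq_along(res$times), function(k) {
      swarm_state(res$traj_positions[[k]], res$traj_velocities[[k]],
                  t = state$t + res$times[k], L = params$L)
    })
  }
  structure(list(
    series = series,
    state = swarm_state(res$positions, res$velocities,
                        t = state$t + n_steps * params$dt, L = params$L),
    n_rebuild = res$n_rebuild, n_clamped = res$n_clamped,
    trajectory = traj, params = params, seed = seed),
    class = "flock_run")
}

#' @export
print.flock_run <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("flock_run: %d recorded frames, t in [%g, %g] s; final E = %.4f\n",
              n, x$series$t[1], x$series$t[n], x$series$E[n]))
  invisible(x)
}
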