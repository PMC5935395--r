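#' Model and simulation parameters
#'
#' Bundle of all physical and numerical constants of the flocking model, in
#' SI units. Defaults are the reference many-agent configuration: N = 200
#' agents in an L = 50 m periodic cube, preferred speed v0 = 5 m/s, speed
#' relaxation time tau = 1 s, unit mass, repulsion constant c = 1 N m^2,
#' interaction cutoff R = 10 m, no noise, midpoint time step dt = 1e-3 s and
#' no interaction delay.
#'
#' @param N agent count (>= 1).
#' @param L box side (m). `floor(L/R)` must be at least 3 so the 27-cell
#'   neighbour search is exhaustive.
#' @param v0 preferred speed (m/s).
#' @param tau speed relaxation time (s); `Inf` disables self-propulsion
#'   (useful for momentum-conservation checks).
#' @param mass agent mass (kg).
#' @param c repulsion constant (N m^2); pair force magnitude is `c / r^2`.
#' @param R interaction cutoff (m); pairs at minimum-image distance `>= R`
#'   do not interact.
#' @param xi noise amplitude (N): the constant magnitude of a random force
#'   whose direction is re-drawn independently for every agent and update.
#'   A simulation update over an interval `h` therefore adds to each
#'   velocity a uniformly oriented impulse of magnitude `xi * h / mass`
#'   (see `noise_scaling`).
#' @param dt integration time step (s).
#' @param t_d interaction delay (s); must be an exact multiple of `dt`.
#'   All deterministic forces are evaluated `t_d` before the current time.
#' @param noise_scaling `"linear"` (default) is the constant-magnitude
#'   force convention: the impulse scales with the interval itself
#'   (`xi * dt` for a full step, `xi * dt/2` for the first half of a
#'   midpoint step), so a free agent's velocity variance grows at rate
#'   `xi^2 * dt / mass^2`. `"sqrt"` scales the impulse with
#'   `sqrt(interval)` instead, making the diffusion rate `xi^2 / mass^2`
#'   independent of the time step; provided for sensitivity checks of the
#'   convention.
#' @param skin candidate-list skin thickness (m) used by the compiled
#'   integrator; purely a performance parameter, results are independent of
#'   it because the true cutoff is applied at every force evaluation.
#'
#' @return An object of class `flock_params` (a named list).
#' @examples
#' p <- model_params(N = 50, L = 31.5)
#' p$R
#' @export
model_params <- function(N = 200, L = 50, v0 = 5, tau = 1, mass = 1,
                         c = 1, R = 10, xi = 0, dt = 1e-3, t_d = 0,
                         noise_scaling = c("linear", "sqrt"), skin = 0.5) {
  noise_scaling <- match.arg(noise_scaling)
  stopifnot(
    length(N) == 1, N >= 1, N == floor(N),
    L > 0, v0 > 0, tau > 0, mass > 0, c > 0, R > 0, dt > 0,
    xi >= 0, t_d >= 0, skin >= 0
  )
  if (floor(L / R) < 3) {
    stop("floor(L/R) = ", floor(L / R),
         " but must be >= 3 for an exhaustive 27-cell neighbour search")
  }
  k <- t_d / dt
  if (abs(k - round(k)) > 1e-9 * max(1, k)) {
    stop("t_d must be an exact integer multiple of dt (t_d/dt = ", k, ")")
  }
  structure(
    list(N = as.integer(N), L = L, v0 = v0, tau = tau, mass = mass,
         c = c, R = R, xi = xi, dt = dt, t_d = t_d,
         delay_steps = as.integer(round(k)),
         noise_scaling = noise_scaling, skin = skin),
    class = "flock_params")
}

#' @export
print.flock_params <- function(x, ...) {
  cat("flock3d model parameters\n")
  cat(sprintf("  N = %d agents, box L = %g m (periodic), density N/L^3 = %.3g m^-3\n",
              x$N, x$L, x$N / x$L^3))
  cat(sprintf("  v0 = %g m/s, tau = %g s, m = %g kg, c = %g N m^2, R = %g m\n",
              x$v0, x$tau, x$mass, x$c, x$R))
  cat(sprintf("  xi = %g N (%s scaling), dt = %g s, t_d = %g s (%d steps)\n",
              x$xi, x$noise_scaling, x$dt, x$t_d, x$delay_steps))
  invisible(x)
}

#' Scaled-down preset parameters
#'
#' Desk-scale configuration holding the reference number density
#' N/L^3 = 200/50^3 = 0.0016 m^-3 fixed while reducing the agent count, so
#' transition experiments run on a single core in minutes. For `N = 50` the
#' box side becomes (50/0.0016)^(1/3) = 31.498 m, which still satisfies
#' `floor(L/R) >= 3`.
#'
#' @param N agent count for the scaled system (default 50; values below ~43
#'   would violate the grid constraint at this density).
#' @param ... further overrides passed to [model_params()].
#' @return A `flock_params` object.
#' @examples
#' desk_params()$L
#' @export
desk_params <- function(N = 50, ...) {
  density <- 200 / 50^3
  model_params(N = N, L = (N / density)^(1 / 3), ...)
}

#' Swarm state
#'
#' Per-agent positions and velocities at a simulation time. Positions are
#' coordinates in the periodic box, each component in `[0, L)`.
#'
#' @param positions N x 3 numeric matrix (m), each coordinate in `[0, L)`.
#' @param velocities N x 3 numeric matrix (m/s).
#' @param t simulation time (s).
#' @param L box side (m), used only to validate the positions.
#' @return An object of class `swarm_state`: a list with elements `t`,
#'   `positions`, `velocities`.
#' @examples
#' s <- swarm_state(matrix(1, 1, 3), matrix(c(5, 0, 0), 1, 3), t = 0, L = 50)
#' @export
swarm_state <- function(positions, velocities, t = 0, L = NULL) {
  positions <- as.matrix(positions)
  velocities <- as.matrix(velocities)
  stopifnot(ncol(positions) == 3, ncol(velocities) == 3,
            nrow(positions) == nrow(velocities),
            all(is.finite(positions)), all(is.finite(velocities)),
            length(t) == 1, is.finite(t))
  if (!is.null(L)) {
    if (any(positions < 0) || any(positions >= L)) {
      stop("position components must lie in [0, L)")
    }
  }
  structure(list(t = t, positions = unname(positions),
                 velocities = unname(velocities)),
            class = "swarm_state")
}

#' @export
print.swarm_state <- function(x, ...) {
  N <- nrow(x$positions)
  sp <- sqrt(rowSums(x$velocities^2))
  cat(sprintf("swarm_state: %d agents at t = %g s; speeds %.3g-%.3g m/s\n",
              N, x$t, min(sp), max(sp)))
  invisible(x)
}

check_state <- function(state, params) {
  stopifnot(inherits(state, "swarm_state"))
  if (nrow(state$positions) != params$N) {
    stop("state has ", nrow(state$positions), " agents but params$N = ", params$N)
  }
  invisible(state)
}
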