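#' Configuration of the symmetric two-agent encounter
#'
#' Geometry and numerics of the two-agent scattering experiment. Two
#' identical agents move so that their states remain mirror images under a
#' half-turn about the axis joining the midpoints of their parallel
#' velocity planes: the planes are a distance `d` apart, the projected
#' (plane-view) separation starts at `D0 = 1000` m, the projected velocity
#' vectors enclose the angle `phi`, and integration stops when the
#' projected separation reaches `D_stop = 1100` m. The interaction cutoff
#' and the periodic box are disabled here; forward Euler with step `dt` is
#' used throughout.
#'
#' @param d separation of the two velocity planes (m), `> 0`.
#' @param phi initial angle between the velocity vectors (degrees), in
#'   (0, 180]. `phi = 0` is rejected: the agents would never converge.
#' @param dt Euler time step (s); 1e-5 for production maps, 1e-4 is
#'   adequate per the convergence analysis ([dt_convergence()]).
#' @param D0,D_stop initial and terminal projected separations (m).
#' @param v0,tau,c,mass model constants (see [model_params()]).
#' @param max_time integration budget (s).
#' @return An object of class `encounter_config`.
#' @examples
#' encounter_config(d = 2, phi = 60)
#' @export
encounter_config <- function(d, phi, dt = 1e-5, D0 = 1000, D_stop = 1100,
                             v0 = 1, tau = 1, c = 1, mass = 1,
                             max_time = 1e5) {
  stopifnot(d > 0, phi > 0, phi <= 180, dt > 0, D_stop > D0, D0 > 0,
            v0 > 0, tau > 0, c > 0, mass > 0, max_time > 0)
  structure(list(d = d, phi = phi, dt = dt, D0 = D0, D_stop = D_stop,
                 v0 = v0, tau = tau, c = c, mass = mass,
                 max_time = max_time),
            class = "encounter_config")
}

#' Initial state of the symmetric encounter
#'
#' Realizes the mirror-symmetric geometry: agent 1 at
#' `(-D0/2, 0, +d/2)` with velocity `v0 (sin(phi/2), cos(phi/2), 0)`,
#' agent 2 at `(+D0/2, 0, -d/2)` with velocity
#' `v0 (-sin(phi/2), cos(phi/2), 0)`. Viewed along z the agents are `D0`
#' apart and their velocities enclose `phi`; the configuration is invariant
#' under a half-turn about the y axis through the center of mass, a
#' symmetry the dynamics preserves. No periodic wrap applies.
#'
#' @param config an [encounter_config()].
#' @return A [swarm_state()] with two agents at `t = 0`.
#' @examples
#' st <- setup_encounter(encounter_config(d = 2, phi = 60))
#' colSums(st$velocities)  # total momentum 2 v0 cos(30 deg) along +y
#' @export
setup_encounter <- function(config) {
  stopifnot(inherits(config, "encounter_config"))
  half <- config$phi / 2 * pi / 180
  sh <- sin(half); ch <- cos(half)
  pos <- rbind(c(-config$D0 / 2, 0, config$d / 2),
               c(config$D0 / 2, 0, -config$d / 2))
  vel <- config$v0 * rbind(c(sh, ch, 0), c(-sh, ch, 0))
  swarm_state(pos, vel, t = 0)
}

#' Run the symmetric two-agent encounter
#'
#' Forward-Euler integration (no noise, no cutoff, no periodic box) until
#' the projected separation reaches `D_stop`. The headline quantity is
#' `delta_I`, the change in the magnitude of the total momentum over the
#' encounter: positive `delta_I` means the pair departs more aligned than
#' it arrived. By symmetry the total momentum stays on the y axis, so
#' `delta_I` reduces to the change in its y component.
#'
#' @param config an [encounter_config()].
#' @param sym_check_every check mirror-symmetry preservation every this
#'   many steps (0 disables); the maximum relative asymmetry observed is
#'   reported.
#' @return A list of class `encounter_result`: `delta_I` (kg m/s), `steps`,
#'   `elapsed` (s), `closest_approach` (m), `p_initial`, `p_final`,
#'   `max_asymmetry`, and the final two-agent `state`.
#' @examples
#' \donttest{
#' run_encounter(encounter_config(d = 2, phi = 60, dt = 1e-4))$delta_I
#' }
#' @export
run_encounter <- function(config, sym_check_every = 1000) {
  stopifnot(inherits(config, "encounter_config"))
  res <- run_encounter_cpp(config$d, config$phi, config$dt, config$D0,
                           config$D_stop, config$v0, config$tau, config$c,
                           config$mass, config$max_time,
                           as.integer(sym_check_every))
  structure(list(delta_I = res$delta_I, steps = res$steps,
                 elapsed = res$elapsed,
                 closest_approach = res$closest_approach,
                 p_initial = res$p_initial, p_final = res$p_final,
                 max_asymmetry = res$max_asymmetry,
                 state = swarm_state(res$positions, res$velocities,
                                     t = res$elapsed),
                 config = config),
            class = "encounter_result")
}

#' @export
print.encounter_result <- function(x, ...) {
  cat(sprintf(
    "encounter: d = %g m, phi = %g deg, dt = %g s -> delta_I = %+.4e kg m/s (closest approach %.3g m, %g steps)\n",
    x$config$d, x$config$phi, x$config$dt, x$delta_I,
    x$closest_approach, x$steps))
  invisible(x)
}

#' Alignment threshold angle
#'
#' The initial angle at which `delta_I` changes sign for a given plane
#' separation `d`: below the threshold the encounter reduces the pair's
#' total momentum, above it the pair departs more aligned. Located by a
#' coarse scan over `[phi_lo, phi_hi]` followed by bisection to the
#' requested angular resolution.
#'
#' @param d plane separation (m).
#' @param phi_lo,phi_hi scan bracket (degrees).
#' @param resolution terminal bisection width (degrees).
#' @param dt Euler step (s).
#' @param coarse_step coarse scan spacing (degrees).
#' @param ... passed to [encounter_config()].
#' @return Threshold angle (degrees). Errors, reporting `delta_I` at both
#'   bracket ends, when no sign change lies in the bracket.
#' @examples
#' \donttest{
#' threshold_angle(d = 2, dt = 1e-4)
#' }
#' @export
threshold_angle <- function(d, phi_lo = 30, phi_hi = 60, resolution = 0.5,
                            dt = 1e-4, coarse_step = 5, ...) {
  stopifnot(phi_lo < phi_hi, resolution > 0, coarse_step > 0)
  dI <- function(phi) {
    run_encounter(encounter_config(d = d, phi = phi, dt = dt, ...),
                  sym_check_every = 0)$delta_I
  }
  phis <- unique(c(seq(phi_lo, phi_hi, by = coarse_step), phi_hi))
  vals <- vapply(phis, dI, numeric(1))
  sgn <- sign(vals)
  cross <- which(sgn[-length(sgn)] < 0 & sgn[-1] >= 0)
  if (length(cross) == 0) {
    stop(sprintf(
      "no sign change of delta_I in [%g, %g] deg at d = %g m (delta_I = %.3e at %g deg, %.3e at %g deg)",
      phi_lo, phi_hi, d, vals[1], phis[1], vals[length(vals)],
      phis[length(phis)]))
  }
  lo <- phis[cross[1]]; hi <- phis[cross[1] + 1]
  flo <- vals[cross[1]]
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    fm <- dI(mid)
    if (sign(fm) == sign(flo) && fm != 0) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Integration-step sensitivity of the encounter
#'
#' Maximum absolute discrepancy of `delta_I` between a coarse and a fine
#' Euler step across a set of `(d, phi)` points — the numerical-error
#' control of the encounter experiment (first-order in the coarse step).
#'
#' @param points data.frame (or matrix) with columns `d` and `phi`.
#' @param dt_coarse,dt_fine the two Euler steps to compare (s).
#' @param ... passed to [encounter_config()].
#' @return A list: `max_diff` (kg m/s) and a `table` with `delta_I` at both
#'   steps and the per-point difference.
#' @examples
#' \donttest{
#' dt_convergence(data.frame(d = 2, phi = 55), 1e-3, 1e-4)$max_diff
#' }
#' @export
dt_convergence <- function(points, dt_coarse = 1e-4, dt_fine = 1e-5, ...) {
  points <- as.data.frame(points)
  stopifnot(nrow(points) >= 1, all(c("d", "phi") %in% names(points)))
  res <- lapply(seq_len(nrow(points)), function(k) {
    a <- run_encounter(encounter_config(d = points$d[k], phi = points$phi[k],
                                        dt = dt_coarse, ...),
                       sym_check_every = 0)$delta_I
    b <- run_encounter(encounter_config(d = points$d[k], phi = points$phi[k],
                                        dt = dt_fine, ...),
                       sym_check_every = 0)$delta_I
    data.frame(d = points$d[k], phi = points$phi[k],
               delta_I_coarse = a, delta_I_fine = b, diff = abs(a - b))
  })
  tab <- do.call(rbind, res)
  list(max_diff = max(tab$diff), table = tab)
}

#' Map the encounter outcome over a (d, phi) grid
#'
#' Convenience scan producing the data behind the alignment map: `delta_I`
#' and the closest approach for every combination of plane separation and
#' initial angle.
#'
#' @param d_values plane separations (m).
#' @param phi_values initial angles (degrees).
#' @param dt Euler step (s).
#' @param ... passed to [encounter_config()].
#' @return data.frame with columns `d`, `phi`, `delta_I`,
#'   `closest_approach`.
#' @examples
#' \donttest{
#' pair_scan(c(2, 5), c(40, 50), dt = 1e-4)
#' }
#' @export
pair_scan <- function(d_values, phi_values, dt = 1e-4, ...) {
  grid <- expand.grid(d = d_values, phi = phi_values)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    r <- run_encounter(encounter_config(d = grid$d[k], phi = grid$phi[k],
                                        dt = dt, ...),
                       sym_check_every = 0)
    data.frame(d = grid$d[k], phi = grid$phi[k], delta_I = r$delta_I,
               closest_approach = r$closest_approach)
  })
  do.call(rbind, rows)
}
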