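#' Self-propulsion force
#'
#' Speed-control term of the equations of motion: a force of magnitude
#' `(mass/tau) * |v0 - |v||` along the agent's own heading, accelerating
#' below the preferred speed and braking above it. At the preferred speed
#' the term vanishes; at `|v| = 0` the heading is undefined and the zero
#' vector is returned (an isotropic choice for a measure-zero event).
#'
#' @param v velocity triple (m/s).
#' @param params a [model_params()] object (uses `v0`, `tau`, `mass`).
#' @return Force triple (N).
#' @examples
#' p <- model_params()
#' propulsion_force(c(2.5, 0, 0), model_params(v0 = 5, tau = 1, mass = 1))
#' @export
propulsion_force <- function(v, params) {
  stopifnot(length(v) == 3, all(is.finite(v)))
  s <- sqrt(sum(v^2))
  if (s == 0) return(c(0, 0, 0))
  mt <- if (is.finite(params$tau)) params$mass / params$tau else 0
  mt * (params$v0 - s) / s * v
}

#' Pairwise radial repulsion
#'
#' Central collision-avoidance force of magnitude `c / r^2` pushing agent i
#' away from agent j, zero at or beyond the cutoff `R` when `apply_cutoff`
#' is `TRUE`. The force on j is the exact negation (Newton's third law).
#'
#' @param disp displacement triple from j to i (m), `r_i - r_j` under the
#'   minimum-image convention.
#' @param params a [model_params()] object (uses `c`, `R`).
#' @param apply_cutoff if `TRUE` (default) the force is exactly zero for
#'   `r >= R`; the two-agent encounter experiment disables the cutoff.
#' @return Force triple on agent i (N).
#' @examples
#' repulsion_force(c(1, 0, 0), model_params(), apply_cutoff = FALSE)
#' @export
repulsion_force <- function(disp, params, apply_cutoff = TRUE) {
  stopifnot(length(disp) == 3, all(is.finite(disp)))
  r2 <- sum(disp^2)
  if (r2 == 0) stop("coincident agents: repulsion undefined at zero separation")
  if (apply_cutoff && r2 >= params$R^2) return(c(0, 0, 0))
  params$c / (r2 * sqrt(r2)) * disp
}

#' Isotropic noise impulse
#'
#' Velocity increment modelling uncorrelated noise over an effective time
#' span: a random force of constant magnitude `xi` acting for `interval`
#' gives an impulse of magnitude `xi * interval / mass` (default `"linear"`
#' convention) in a direction drawn uniformly on the unit sphere,
#' independent across calls and agents. A free agent's velocity then
#' diffuses with variance rate `xi^2 * dt / mass^2`. The `"sqrt"` variant
#' uses magnitude `xi * sqrt(interval) / mass`, making the diffusion rate
#' `xi^2 / mass^2` independent of the step size.
#'
#' @param xi noise amplitude (N); `0` returns zero vectors.
#' @param interval effective time span (s): the full step `dt` for the main
#'   update, `dt/2` for the first half of a midpoint step.
#' @param mass agent mass (kg).
#' @param n number of independent impulses to draw.
#' @param scaling `"linear"` (default) or `"sqrt"`; see [model_params()].
#' @return An `n` x 3 matrix of velocity increments (m/s).
#' @examples
#' set.seed(1)
#' noise_impulse(1, 1, n = 2)
#' @export
noise_impulse <- function(xi, interval, mass = 1, n = 1,
                          scaling = c("linear", "sqrt")) {
  scaling <- match.arg(scaling)
  stopifnot(xi >= 0, interval > 0, mass > 0, n >= 1)
  if (xi == 0) return(matrix(0, n, 3))
  g <- matrix(rnorm(3 * n), n, 3)
  nrm <- sqrt(rowSums(g^2))
  bad <- nrm < 1e-290
  while (any(bad)) {
    g[bad, ] <- rnorm(3 * sum(bad))
    nrm <- sqrt(rowSums(g^2))
    bad <- nrm < 1e-290
  }
  amp <- if (scaling == "sqrt") xi * sqrt(interval) / mass else xi * interval / mass
  g * (amp / nrm)
}

#' Net deterministic forces on every agent
#'
#' Sum of the self-propulsion term and the pairwise repulsion over the
#' supplied neighbour pairs (noise is handled separately by the integrator
#' and never enters here). The pair list must contain exactly the pairs at
#' minimum-image distance below the cutoff, as produced by
#' [neighbor_pairs()]. Repulsion contributions cancel pairwise, so their
#' sum over all agents is the zero vector.
#'
#' @param state a [swarm_state()].
#' @param pairs a pair list from [neighbor_pairs()] (fields `i`, `j`,
#'   `disp`, `dist`).
#' @param params a [model_params()] object.
#' @return N x 3 matrix of forces (N).
#' @examples
#' p <- model_params(N = 2)
#' s <- swarm_state(rbind(c(1, 1, 1), c(2, 1, 1)),
#'                  rbind(c(5, 0, 0), c(5, 0, 0)), L = p$L)
#' net_forces(s, neighbor_pairs(s, p), p)
#' @export
net_forces <- function(state, pairs, params) {
  check_state(state, params)
  v <- state$velocities
  s <- sqrt(rowSums(v^2))
  mt <- if (is.finite(params$tau)) params$mass / params$tau else 0
  fac <- ifelse(s > 0, mt * (params$v0 - s) / s, 0)
  f <- v * fac
  if (length(pairs$i) > 0) {
    if (any(pairs$dist == 0)) stop("coincident agents in pair list")
    w <- params$c / pairs$dist^3
    fv <- pairs$disp * w
    for (k in 1:3) {
      f[, k] <- f[, k] +
        tabulate2(pairs$i, fv[, k], params$N) -
        tabulate2(pairs$j, fv[, k], params$N)
    }
  }
  f
}

# sum `val` into bins `idx` of length n (vectorized accumulation)
tabulate2 <- function(idx, val, n) {
  out <- numeric(n)
  acc <- rowsum(val, idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}
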