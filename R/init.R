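#' Random placement with a minimum pairwise distance
#'
#' Sequential rejection sampling: agents are inserted one by one at uniform
#' positions in the periodic box and re-drawn while any minimum-image
#' distance to an already placed agent falls below `min_dist`. Matches the
#' loosely packed regime of the model (spacing `0.6 * L * N^(-1/3)`), where
#' rejections are rare.
#'
#' @param N number of agents.
#' @param L box side (m).
#' @param min_dist minimum allowed pairwise minimum-image distance (m).
#' @param max_attempts total draw budget before giving up.
#' @return N x 3 matrix of positions in `[0, L)`.
#' @examples
#' set.seed(1)
#' pos <- place_min_dist(10, 50, 5)
#' @export
place_min_dist <- function(N, L, min_dist, max_attempts = 200 * N) {
  stopifnot(N >= 1, L > 0, min_dist >= 0, max_attempts >= N)
  if (min_dist == 0) return(matrix(runif(3 * N, 0, L), N, 3))
  pos <- matrix(NA_real_, N, 3)
  placed <- 0L
  attempts <- 0L
  md2 <- min_dist^2
  while (placed < N) {
    if (attempts >= max_attempts) {
      stop(sprintf(
        "placement budget exhausted after %d attempts (%d/%d placed); packing fraction of exclusion spheres = %.3f",
        attempts, placed, N, N * (4 / 3) * pi * (min_dist / 2)^3 / L^3))
    }
    attempts <- attempts + 1L
    cand <- runif(3, 0, L)
    ok <- TRUE
    if (placed > 0L) {
      d <- min_image_disp(pos[seq_len(placed), , drop = FALSE],
                          matrix(cand, placed, 3, byrow = TRUE), L)
      if (any(rowSums(d^2) < md2)) ok <- FALSE
    }
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
  }
  pos
}

# the model's standard minimum spacing at density N/L^3
default_min_dist <- function(N, L) 0.6 * L * N^(-1 / 3)

#' Disordered initial condition
#'
#' Agents at random positions (no pair closer than `0.6 * L * N^(-1/3)`
#' under the minimum-image metric), every speed exactly `v0`, headings drawn
#' independently and uniformly on the sphere; `t = 0`. The resulting
#' efficiency is O(N^(-1/2)).
#'
#' @param params a [model_params()] object.
#' @param seed optional integer seed.
#' @param min_dist minimum pairwise distance (m); default
#'   `0.6 * L * N^(-1/3)`.
#' @return A [swarm_state()] at `t = 0`.
#' @examples
#' s <- init_disordered(desk_params(), seed = 1)
#' range(sqrt(rowSums(s$velocities^2)))  # all exactly v0
#' @export
init_disordered <- function(params, seed = NULL,
                            min_dist = default_min_dist(params$N, params$L)) {
  if (!is.null(seed)) set.seed(seed)
  pos <- place_min_dist(params$N, params$L, min_dist)
  dir <- matrix(rnorm(3 * params$N), params$N, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  swarm_state(pos, dir * params$v0, t = 0, L = params$L)
}

#' Ordered (equilibrated) initial condition
#'
#' Agents placed as in [init_disordered()] but with all velocity vectors
#' identical (speed `v0`, one random direction shared by every agent), then
#' evolved noiselessly and without delay for an equilibration interval so
#' the spatial structure relaxes; the returned state is relabelled `t = 0`.
#' The reference protocol equilibrates for 1e5 s; scaled-down experiments
#' use proportionally shorter intervals. With `equilibration = 0` the state
#' has efficiency exactly 1.
#'
#' @param params a [model_params()] object.
#' @param seed optional integer seed.
#' @param equilibration equilibration duration (s), `>= 0`.
#' @param min_dist minimum pairwise distance (m).
#' @return A [swarm_state()] at `t = 0`.
#' @examples
#' s <- init_ordered(desk_params(), seed = 1, equilibration = 0)
#' efficiency(s, desk_params())  # exactly 1
#' @export
init_ordered <- function(params, seed = NULL, equilibration = 1e5,
                         min_dist = default_min_dist(params$N, params$L)) {
  stopifnot(equilibration >= 0)
  if (!is.null(seed)) set.seed(seed)
  pos <- place_min_dist(params$N, params$L, min_dist)
  dir <- rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  vel <- matrix(dir * params$v0, params$N, 3, byrow = TRUE)
  st <- swarm_state(pos, vel, t = 0, L = params$L)
  if (equilibration > 0) {
    eq_params <- params
    eq_params$xi <- 0
    eq_params$t_d <- 0
    eq_params$delay_steps <- 0L
    run <- run_sim(st, eq_params, T = equilibration,
                   record_every = equilibration)
    st <- run$state
    st$t <- 0
  }
  st
}
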