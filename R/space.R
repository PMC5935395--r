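#' Wrap positions into the periodic box
#'
#' Maps every coordinate into `[0, L)` by modular arithmetic; idempotent.
#'
#' @param pos coordinate triple or N x 3 matrix (m).
#' @param L box side (m).
#' @return Same shape as `pos`, all components in `[0, L)`.
#' @examples
#' wrap_position(c(51, -1, 25), 50)
#' @export
wrap_position <- function(pos, L) {
  stopifnot(L > 0, all(is.finite(pos)))
  out <- pos - L * floor(pos / L)
  out[out >= L] <- 0  # guard: -eps + L can round to exactly L
  out
}

#' Minimum-image displacement
#'
#' Componentwise `ri - rj` shifted by multiples of `L` into `[-L/2, L/2)`:
#' the displacement to the nearest periodic image, the only distance
#' convention consistent with periodic boundaries.
#'
#' @param ri,rj position triples or N x 3 matrices, components in `[0, L)`.
#' @param L box side (m).
#' @return Displacement (same shape), components in `[-L/2, L/2)`.
#' @examples
#' min_image_disp(c(1, 0, 0), c(49, 0, 0), 50)
#' @export
min_image_disp <- function(ri, rj, L) {
  d <- ri - rj
  d - L * round(d / L)
}

#' Neighbour pairs within the interaction cutoff
#'
#' Exactly the unordered agent pairs whose minimum-image distance is
#' strictly below the cutoff `R`, each reported once with `i < j`. Uses a
#' periodic cell grid (cell side `L/floor(L/R) >= R`, own cell plus 26
#' neighbours), so the search is exhaustive whenever `floor(L/R) >= 3`,
#' which [model_params()] enforces.
#'
#' @param state a [swarm_state()].
#' @param params a [model_params()] object.
#' @return A list with integer vectors `i`, `j` (1-based, `i < j`), the
#'   `disp` matrix of minimum-image displacements `r_i - r_j` (m) and the
#'   `dist` vector (m), all of one row/element per pair.
#' @examples
#' p <- model_params(N = 2)
#' s <- swarm_state(rbind(c(1, 1, 1), c(6, 1, 1)),
#'                  rbind(c(5, 0, 0), c(5, 0, 0)), L = p$L)
#' neighbor_pairs(s, p)$dist
#' @export
neighbor_pairs <- function(state, params) {
  check_state(state, params)
  neighbor_pairs_cpp(state$positions, params$L, params$R)
}
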