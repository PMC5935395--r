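# Independent brute-force oracles used across test files.

# O(N^2) all-pairs neighbour scan under the minimum-image metric
brute_pairs <- function(pos, L, R) {
  N <- nrow(pos)
  out <- list(i = integer(0), j = integer(0), dist = numeric(0))
  if (N < 2) return(out)
  for (a in 1:(N - 1)) {
    for (b in (a + 1):N) {
      d <- pos[a, ] - pos[b, ]
      d <- d - L * round(d / L)
      r <- sqrt(sum(d^2))
      if (r < R) {
        out$i <- c(out$i, a); out$j <- c(out$j, b)
        out$dist <- c(out$dist, r)
      }
    }
  }
  out
}

# displacement to the nearest of the 27 periodic images, by enumeration
brute_min_image <- function(ri, rj, L) {
  best <- NULL; bestn <- Inf
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    d <- ri - (rj + c(sx, sy, sz) * L)
    n <- sum(d^2)
    if (n < bestn) { bestn <- n; best <- d }
  }
  best
}

# double-loop evaluation of the full deterministic force field
brute_forces <- function(state, params) {
  N <- nrow(state$positions)
  f <- matrix(0, N, 3)
  for (a in seq_len(N)) {
    v <- state$velocities[a, ]
    f[a, ] <- propulsion_force(v, params)
  }
  if (N > 1) {
    for (a in 1:(N - 1)) {
      for (b in (a + 1):N) {
        d <- state$positions[a, ] - state$positions[b, ]
        d <- d - params$L * round(d / params$L)
        fr <- repulsion_force(d, params, apply_cutoff = TRUE)
        f[a, ] <- f[a, ] + fr
        f[b, ] <- f[b, ] - fr
      }
    }
  }
  f
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# random valid swarm state at moderate density
random_state <- function(params, seed) {
  set.seed(seed)
  pos <- matrix(runif(3 * params$N, 0, params$L), params$N, 3)
  dir <- matrix(rnorm(3 * params$N), params$N, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  sp <- runif(params$N, 0.5 * params$v0, 1.5 * params$v0)
  swarm_state(pos, dir * sp, t = 0, L = params$L)
}
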