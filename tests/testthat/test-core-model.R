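p_unit <- model_params(N = 1, v0 = 5, tau = 1, mass = 1)

test_that("propulsion force vanishes at the preferred speed and points along the heading", {
  expect_equal(propulsion_force(c(5, 0, 0), p_unit), c(0, 0, 0))
  expect_equal(propulsion_force(c(2.5, 0, 0), p_unit), c(2.5, 0, 0))
  expect_equal(propulsion_force(c(0, 0, 10), p_unit), c(0, 0, -5))
  # heading undefined at rest: isotropic zero-force convention
  expect_equal(propulsion_force(c(0, 0, 0), p_unit), c(0, 0, 0))
  # tau = Inf disables self-propulsion
  expect_equal(propulsion_force(c(1, 2, 3), model_params(tau = Inf)), c(0, 0, 0))
})

test_that("propulsion force is rotation-equivariant", {
  set.seed(42)
  for (k in 1:20) {
    Q <- random_rotation()
    v <- rnorm(3) * runif(1, 0.1, 10)
    expect_equal(as.numeric(Q %*% propulsion_force(v, p_unit)),
                 propulsion_force(as.numeric(Q %*% v), p_unit),
                 tolerance = 1e-12)
  }
})

test_that("repulsion follows the inverse-square law with a strict cutoff", {
  p <- model_params()
  expect_equal(repulsion_force(c(1, 0, 0), p, apply_cutoff = FALSE), c(1, 0, 0))
  expect_equal(repulsion_force(c(0, 2, 0), p, apply_cutoff = FALSE), c(0, 0.25, 0))
  expect_equal(repulsion_force(c(12, 0, 0), p, apply_cutoff = TRUE), c(0, 0, 0))
  # exactly at the cutoff the pair does not interact (distance strictly < R)
  expect_equal(repulsion_force(c(10, 0, 0), p, apply_cutoff = TRUE), c(0, 0, 0))
  # antisymmetry
  d <- c(1.3, -0.7, 2.2)
  expect_equal(repulsion_force(d, p, FALSE), -repulsion_force(-d, p, FALSE))
  expect_error(repulsion_force(c(0, 0, 0), p), "coincident")
})

test_that("noise impulses have the advertised magnitude and are isotropic", {
  expect_equal(noise_impulse(0, 1, n = 3), matrix(0, 3, 3))
  set.seed(7)
  # linear (constant-force) convention: |impulse| = xi * interval / mass
  v <- noise_impulse(2, 0.5, mass = 4, n = 100, scaling = "linear")
  expect_equal(sqrt(rowSums(v^2)), rep(2 * 0.5 / 4, 100), tolerance = 1e-12)
  v <- noise_impulse(1, 0.25, mass = 1, n = 10, scaling = "sqrt")
  expect_equal(sqrt(rowSums(v^2)), rep(0.5, 10), tolerance = 1e-12)
  # Monte-Carlo isotropy at xi = 1, interval = 1: per-component mean is 0
  # with SE sqrt(1/3/n); mean squared magnitude is exactly interval
  n <- 2e4
  set.seed(11)
  v <- noise_impulse(1, 1, n = n, scaling = "linear")
  se <- sqrt(1 / 3 / n)
  expect_true(all(abs(colMeans(v)) < 3 * se))
  expect_equal(mean(rowSums(v^2)), 1, tolerance = 1e-12)
})

test_that("net forces match a brute-force double-loop evaluation", {
  p <- model_params(N = 20)
  for (seed in c(1, 2, 3)) {
    st <- random_state(p, seed)
    f <- net_forces(st, neighbor_pairs(st, p), p)
    expect_equal(f, brute_forces(st, p), tolerance = 1e-12)
  }
})

test_that("net force reduces to pure repulsion/propulsion in simple cases", {
  p1 <- model_params(N = 1)
  st <- swarm_state(matrix(25, 1, 3), matrix(c(5, 0, 0), 1, 3), L = p1$L)
  expect_equal(net_forces(st, neighbor_pairs(st, p1), p1), matrix(0, 1, 3))
  # two agents 1 m apart, both at preferred speed: only repulsion remains
  p2 <- model_params(N = 2)
  st <- swarm_state(rbind(c(10, 10, 10), c(11, 10, 10)),
                    rbind(c(0, 5, 0), c(0, 5, 0)), L = p2$L)
  f <- net_forces(st, neighbor_pairs(st, p2), p2)
  expect_equal(f, rbind(c(-1, 0, 0), c(1, 0, 0)), tolerance = 1e-12)
})

test_that("repulsive forces cancel pairwise (Newton's third law)", {
  # at speed v0 the propulsion term is zero, so the total force is the
  # total repulsion, which must vanish componentwise
  p <- model_params(N = 60)
  for (seed in 4:8) {
    st <- random_state(p, seed)
    st$velocities <- st$velocities /
      sqrt(rowSums(st$velocities^2)) * p$v0
    f <- net_forces(st, neighbor_pairs(st, p), p)
    expect_true(all(abs(colSums(f)) < 1e-10))
  }
})
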