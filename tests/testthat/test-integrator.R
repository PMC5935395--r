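# single free agent: speed relaxes as v(t) = v0 + (v(0) - v0) exp(-t/tau)
relax_exact <- function(s0, t, v0 = 5, tau = 1) v0 + (s0 - v0) * exp(-t / tau)

single_state <- function(p, speed) {
  swarm_state(matrix(p$L / 2, 1, 3), matrix(c(speed, 0, 0), 1, 3), L = p$L)
}

test_that("one Euler step reproduces the explicit update", {
  p <- model_params(N = 1, dt = 1e-3)
  st <- euler_step(single_state(p, 5), p)
  expect_equal(st$velocities, matrix(c(5, 0, 0), 1, 3))
  expect_equal(st$positions, matrix(c(25 + 5e-3, 25, 25), 1, 3))
  expect_equal(st$t, 1e-3)
  st <- euler_step(single_state(p, 10), p)
  expect_equal(st$velocities[1, 1], 9.995)
})

test_that("midpoint speed relaxation matches the closed form with O(dt^2) error", {
  p <- model_params(N = 1, dt = 1e-2)
  r <- run_sim(single_state(p, 10), p, T = 1, record_every = 1)
  err1 <- abs(r$state$velocities[1, 1] - relax_exact(10, 1))
  expect_lt(err1, 1e-3)
  p2 <- model_params(N = 1, dt = 5e-3)
  r2 <- run_sim(single_state(p2, 10), p2, T = 1, record_every = 1)
  err2 <- abs(r2$state$velocities[1, 1] - relax_exact(10, 1))
  expect_gt(err1 / err2, 3.3)  # second order: halving dt -> ~4x smaller error
  expect_lt(err1 / err2, 4.7)
})

test_that("Euler relaxation error is first order in dt", {
  p <- model_params(N = 1, dt = 1e-2)
  st <- single_state(p, 10)
  for (k in 1:100) st <- euler_step(st, p)
  err1 <- abs(st$velocities[1, 1] - relax_exact(10, 1))
  p2 <- model_params(N = 1, dt = 5e-3)
  st <- single_state(p2, 10)
  for (k in 1:200) st <- euler_step(st, p2)
  err2 <- abs(st$velocities[1, 1] - relax_exact(10, 1))
  expect_gt(err1 / err2, 1.6)  # first order: halving dt -> ~2x smaller error
  expect_lt(err1 / err2, 2.4)
})

test_that("the R-level midpoint step reproduces the compiled trajectory", {
  p <- model_params(N = 10, L = 30)
  st <- init_disordered(p, seed = 3)
  r <- run_sim(st, p, T = 20 * p$dt, record_every = 20 * p$dt)
  st_r <- st
  for (k in 1:20) st_r <- midpoint_step(st_r, p)
  expect_equal(st_r$positions, r$state$positions, tolerance = 1e-12)
  expect_equal(st_r$velocities, r$state$velocities, tolerance = 1e-12)
})

test_that("the R-level delayed midpoint step reproduces the compiled delayed trajectory", {
  p <- model_params(N = 10, L = 30, t_d = 3e-3)  # 3-step delay
  st <- init_disordered(p, seed = 4)
  r <- run_sim(st, p, T = 15 * p$dt, record_every = 15 * p$dt)
  st_r <- st
  h <- force_history(p$delay_steps)
  for (k in 1:15) {
    st_r <- midpoint_step(st_r, p, history = h)
    h <- attr(st_r, "force_history")
  }
  expect_equal(st_r$positions, r$state$positions, tolerance = 1e-12)
  expect_equal(st_r$velocities, r$state$velocities, tolerance = 1e-12)
})

test_that("zero delay with the history machinery is bitwise identical to the plain path", {
  p <- desk_params()
  st <- init_disordered(p, seed = 1)
  r_plain <- run_sim(st, p, T = 2, record_every = 0.1, use_history = FALSE)
  r_hist <- run_sim(st, p, T = 2, record_every = 0.1, use_history = TRUE)
  expect_identical(r_plain$state$positions, r_hist$state$positions)
  expect_identical(r_plain$state$velocities, r_hist$state$velocities)
  expect_identical(r_plain$series$E, r_hist$series$E)
})

test_that("central repulsion conserves total momentum", {
  # propulsion disabled (tau = Inf), two agents repelling inside the cutoff
  p <- model_params(N = 2, tau = Inf, dt = 1e-3)
  st <- swarm_state(rbind(c(24.5, 25, 25), c(25.5, 25, 25)),
                    rbind(c(0.3, 0.1, 0), c(-0.3, 0.1, 0)), L = p$L)
  ptot0 <- colSums(st$velocities) * p$mass
  r <- run_sim(st, p, T = 10, record_every = 10)  # 1e4 steps
  ptot <- colSums(r$state$velocities) * p$mass
  expect_lt(max(abs(ptot - ptot0)), 1e-8)
})

test_that("runs are reproducible from the seed and record the full cadence", {
  p <- desk_params(xi = 10)
  st <- init_disordered(p, seed = 2)
  r1 <- run_sim(st, p, T = 10 * p$dt, record_every = p$dt, seed = 42)
  r2 <- run_sim(st, p, T = 10 * p$dt, record_every = p$dt, seed = 42)
  r3 <- run_sim(st, p, T = 10 * p$dt, record_every = p$dt, seed = 43)
  expect_equal(nrow(r1$series), 11)  # includes t = 0
  expect_identical(r1$series$E, r2$series$E)
  expect_false(identical(r1$series$E, r3$series$E))
  expect_identical(r1$state$positions, r2$state$positions)
})

test_that("free-agent velocity variance grows linearly at the convention's rate", {
  # tau = Inf and a single agent leave only the full-step noise impulses:
  # after n steps E|v - v(0)|^2 = n * amp^2
  M <- 200; nstep <- 500
  for (sc in c("linear", "sqrt")) {
    p <- model_params(N = 1, tau = Inf, xi = 1, dt = 1e-2,
                      noise_scaling = sc)
    amp2 <- if (sc == "linear") (p$xi * p$dt)^2 else p$xi^2 * p$dt
    disp2 <- numeric(M)
    set.seed(99)
    for (m in 1:M) {
      st <- single_state(p, 0)
      r <- run_sim(st, p, T = nstep * p$dt, record_every = nstep * p$dt)
      disp2[m] <- sum(r$state$velocities^2)
    }
    expect_equal(mean(disp2), nstep * amp2, tolerance = 0.15)
  }
})

test_that("interaction delay changes the trajectory and warm-up is clamped", {
  p0 <- model_params(N = 20, L = 30)
  p1 <- model_params(N = 20, L = 30, t_d = 5e-3)
  st <- init_disordered(p0, seed = 9)
  r0 <- run_sim(st, p0, T = 1, record_every = 1)
  r1 <- run_sim(st, p1, T = 1, record_every = 1)
  expect_gt(max(abs(r0$state$positions - r1$state$positions)), 0)
  expect_equal(r1$n_clamped, 5)  # one clamped lookup per warm-up step
})
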