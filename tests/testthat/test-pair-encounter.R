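test_that("the encounter geometry realizes the mirror-symmetric setup", {
  st <- setup_encounter(encounter_config(d = 2, phi = 60))
  # total momentum 2 v0 cos(phi/2) along +y
  expect_equal(colSums(st$velocities), c(0, 2 * cos(pi / 6), 0),
               tolerance = 1e-12)
  # projected (xy) separation D0, full 3-D separation sqrt(D0^2 + d^2)
  d3 <- st$positions[1, ] - st$positions[2, ]
  expect_equal(sqrt(sum(d3[1:2]^2)), 1000)
  expect_equal(sqrt(sum(d3^2)), sqrt(1000^2 + 2^2))
  # velocities enclose the angle phi at speed v0
  v <- st$velocities
  expect_equal(sqrt(rowSums(v^2)), c(1, 1))
  cosang <- sum(v[1, ] * v[2, ])
  expect_equal(acos(cosang) * 180 / pi, 60, tolerance = 1e-10)
  # antiparallel projected motion has zero total momentum
  st180 <- setup_encounter(encounter_config(d = 3, phi = 180))
  expect_equal(sqrt(sum(colSums(st180$velocities)^2)), 0, tolerance = 1e-12)
  # phi = 0 would never converge
  expect_error(encounter_config(d = 2, phi = 0))
})

test_that("encounters align above the threshold and anti-align below it", {
  lo <- run_encounter(encounter_config(d = 2, phi = 35, dt = 1e-3))
  hi <- run_encounter(encounter_config(d = 2, phi = 55, dt = 1e-3))
  expect_lt(lo$delta_I, 0)
  expect_gt(hi$delta_I, 0)
  expect_gt(lo$closest_approach, 0)
})

test_that("the head-on symmetric encounter leaves zero total momentum", {
  r <- run_encounter(encounter_config(d = 2, phi = 180, dt = 1e-3))
  expect_equal(r$p_initial, 0, tolerance = 1e-12)
  expect_lt(abs(r$delta_I), 1e-9)
})

test_that("mirror symmetry is preserved along the whole trajectory", {
  for (cfg in list(c(2, 50), c(5, 40))) {
    r <- run_encounter(encounter_config(d = cfg[1], phi = cfg[2], dt = 1e-3),
                       sym_check_every = 100)
    expect_lt(r$max_asymmetry, 1e-9)
    # total momentum stays on the y axis
    ptot <- colSums(r$state$velocities)
    expect_lt(max(abs(ptot[c(1, 3)])), 1e-9)
  }
})

test_that("the interaction weakens with the plane separation", {
  # beyond the interaction scale (the sign change sits near d ~ 6 m at
  # phi = 50 deg) the momentum change decays monotonically toward zero
  dI <- vapply(c(20, 50, 200, 500), function(d) {
    run_encounter(encounter_config(d = d, phi = 50, dt = 1e-3),
                  sym_check_every = 0)$delta_I
  }, numeric(1))
  expect_true(all(dI < 0))
  expect_true(all(diff(abs(dI)) < 0))
})

test_that("the threshold angle is a bracketed sign change located consistently", {
  th1 <- threshold_angle(d = 2, dt = 2e-3, resolution = 1)
  th2 <- threshold_angle(d = 2, dt = 2e-3, resolution = 0.1)
  expect_lt(abs(th1 - th2), 1)
  # delta_I has the right sign on both sides of the reported threshold
  below <- run_encounter(encounter_config(d = 2, phi = th2 - 3, dt = 2e-3),
                         sym_check_every = 0)$delta_I
  above <- run_encounter(encounter_config(d = 2, phi = th2 + 3, dt = 2e-3),
                         sym_check_every = 0)$delta_I
  expect_lt(below, 0)
  expect_gt(above, 0)
  # no sign change in a bracket entirely above the threshold
  expect_error(threshold_angle(d = 2, phi_lo = 55, phi_hi = 65, dt = 2e-3),
               "no sign change")
})

test_that("the Euler error in delta_I is first order in dt", {
  pts <- data.frame(d = 2, phi = 45)
  ref <- 1e-4
  c4 <- dt_convergence(pts, dt_coarse = 4e-3, dt_fine = ref)$max_diff
  c2 <- dt_convergence(pts, dt_coarse = 2e-3, dt_fine = ref)$max_diff
  expect_identical(dt_convergence(pts, 1e-3, 1e-3)$max_diff, 0)
  # (4 dt - ref) / (2 dt - ref) ~ 2.05 for linear error in dt
  expect_gt(c4 / c2, 1.5)
  expect_lt(c4 / c2, 2.7)
})

test_that("pair scans tabulate the encounter map", {
  tab <- pair_scan(c(2, 5), c(40, 55), dt = 2e-3)
  expect_equal(nrow(tab), 4)
  expect_named(tab, c("d", "phi", "delta_I", "closest_approach"))
  expect_true(all(is.finite(tab$delta_I)))
})
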