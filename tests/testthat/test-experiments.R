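desk_small <- function(...) desk_params(...)

test_that("experiment specs validate their inputs and warn on huge budgets", {
  sp <- experiment_spec("order_transition", desk_small(), runs = 3,
                        horizon = 10)
  expect_s3_class(sp, "experiment_spec")
  expect_equal(sp$seeds, 1:3)
  expect_error(experiment_spec("order_transition", desk_small(), runs = 2,
                               seeds = c(7L, 7L)))
  expect_warning(
    experiment_spec("order_transition", desk_small(), runs = 1,
                    horizon = 1e7, step_budget = 1e6),
    "budget")
})

test_that("order transition ensembles report per-run series and summaries", {
  sp <- experiment_spec("order_transition", desk_small(), runs = 3,
                        horizon = 40, record_every = 2)
  ot <- order_transition(sp)
  expect_equal(nrow(ot$summary), 3)
  expect_equal(sort(unique(ot$series$run)), 1:3)
  # 21 frames per run including t = 0
  expect_equal(nrow(ot$mean_E), 21)
  expect_true(all(tapply(ot$histogram$histogram$count,
                         ot$histogram$histogram$time_bin, sum) == 3))
  # disordered starts at this horizon stay near the random baseline
  expect_true(all(ot$summary$tail_E < 0.5))
  # provenance: every row carries seed and parameter signature
  expect_true(all(nchar(ot$summary$signature) > 0))
  # reproducibility: same spec, same outputs
  ot2 <- order_transition(sp)
  expect_identical(ot$series$E, ot2$series$E)
})

test_that("a single short run yields a one-frame series", {
  sp <- experiment_spec("order_transition", desk_small(), runs = 1,
                        horizon = desk_small()$dt,
                        record_every = desk_small()$dt)
  ot <- order_transition(sp)
  expect_equal(nrow(ot$series), 2)  # t = 0 and t = dt
})

test_that("the delay sweep at t_d = 0 reproduces plain order-transition runs", {
  p <- desk_small()
  sp_d <- experiment_spec("delay_sweep", p, runs = 2, horizon = 20,
                          record_every = 1, delay_grid = c(0, 0.01))
  ds <- delay_sweep(sp_d)
  sp_o <- experiment_spec("order_transition", p, runs = 2, horizon = 20,
                          record_every = 1)
  ot <- order_transition(sp_o)
  for (k in 1:2) {
    a <- ds$series[ds$series$t_d == 0 & ds$series$start == "disordered" &
                     ds$series$run == k, c("t", "E")]
    b <- ot$series[ot$series$run == k, c("t", "E")]
    expect_equal(a$E, b$E)
  }
  # the delayed condition actually differs
  d10 <- ds$series[ds$series$t_d == 0.01 & ds$series$start == "disordered" &
                     ds$series$run == 1, "E"]
  d0 <- ds$series[ds$series$t_d == 0 & ds$series$start == "disordered" &
                    ds$series$run == 1, "E"]
  expect_false(identical(d10, d0))
  # grid entries must be multiples of dt
  expect_error(delay_sweep(
    experiment_spec("delay_sweep", p, runs = 1, horizon = 1,
                    delay_grid = 0.0005 + 1e-5)), "multiple")
})

test_that("noise hysteresis tabulates both start modes over the grid", {
  p <- desk_small()
  sp <- experiment_spec("noise_hysteresis", p, runs = 2, horizon = 30,
                        record_every = 2, xi_grid = c(0, 0.5),
                        equilibration = 20)
  nh <- noise_hysteresis(sp)
  expect_equal(nrow(nh$runs), 2 * 2 * 2)  # xi x start x runs
  expect_setequal(nh$summary$start, c("disordered", "ordered"))
  expect_equal(nrow(nh$hysteresis), 2)
  # noiseless ordered starts remain ordered over a short horizon
  e0 <- nh$summary$tail_E[nh$summary$xi == 0 & nh$summary$start == "ordered"]
  expect_gt(e0, 0.9)
  expect_type(nh$hysteresis$hysteresis, "logical")
})
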