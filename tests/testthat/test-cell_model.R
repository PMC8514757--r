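# Ionic cell model: equilibrium, excitability, convergence, APD
# measurement, I_Ks calibration.

test_that("resting equilibrium is a fixed point and a stimulus fires an AP", {
  p <- cell_params()
  rest <- cell_resting_state(p)
  out <- step_cell(rest, p, i_stim = 0, dt = 0.02, n_steps = 1000)
  expect_lt(abs(out$state[["vm"]] - rest[["vm"]]), 0.1)

  # -52 uA/uF for 1 ms from rest: suprathreshold, vm exceeds 0 mV in 5 ms
  mid <- step_cell(rest, p, i_stim = -52, dt = 0.02, n_steps = 50)
  fired <- step_cell(mid$state, p, i_stim = 0, dt = 0.02, n_steps = 200,
                     record_stride = 10)
  expect_gt(max(fired$vm), 0)
})

test_that("step halving changes the trajectory by less than 0.01 mV", {
  p <- cell_params()
  rest <- cell_resting_state(p)
  # excite, then compare a plateau-phase step at dt vs dt/2
  st <- step_cell(rest, p, i_stim = -52, dt = 0.02, n_steps = 50)$state
  st <- step_cell(st, p, dt = 0.02, n_steps = 500)$state
  a <- step_cell(st, p, dt = 0.02, n_steps = 1)$state
  b <- step_cell(st, p, dt = 0.01, n_steps = 2)$state
  expect_lt(abs(a[["vm"]] - b[["vm"]]), 0.01)
})

test_that("gates stay in [0,1] and concentrations positive over 30 beats", {
  p <- cell_params("border_zone")
  rest <- cell_resting_state(p)
  out <- vtgrad:::cpp_pace_cell(rest, vtgrad:::mult_vector(p), 0.02, 400, 30L, -52,
                       1, 0L)
  st <- out$state
  gates <- st[2:14]
  expect_true(all(gates >= 0 & gates <= 1))
  expect_true(all(st[15:19] > 0))
})

test_that("APD90 decreases strictly with the I_Ks scale and border-zone APD exceeds normal", {
  apd <- vapply(c(1, 1.25, 1.5, 1.75, 2, 2.25), function(s)
    suppressWarnings(measure_apd90(cell_params(iks_scale = s),
                                   n_beats = 20)$apd90), numeric(1))
  expect_true(all(diff(apd) < 0))

  bz <- suppressWarnings(measure_apd90(cell_params("border_zone"),
                                       n_beats = 20)$apd90)
  expect_gt(bz, apd[1])
})

test_that("APD90 is step-size converged to < 0.5 ms", {
  a <- suppressWarnings(measure_apd90(cell_params(), n_beats = 20,
                                      dt = 0.02)$apd90)
  b <- suppressWarnings(measure_apd90(cell_params(), n_beats = 20,
                                      dt = 0.01)$apd90)
  expect_lt(abs(a - b), 0.5)
})

test_that("gKs calibration is an identity at the model's own APD and monotone", {
  own <- suppressWarnings(measure_apd90(cell_params(), n_beats = 20)$apd90)
  m <- calibrate_base_gks(own, tol = 0.5, n_beats = 20)
  expect_lt(abs(m - 1), 0.01)
  m310 <- calibrate_base_gks(310, tol = 1, n_beats = 20)
  m290 <- calibrate_base_gks(290, tol = 1, n_beats = 20)
  expect_lt(m310, m290)
})

test_that("degenerate pacing and parameter validation error informatively", {
  expect_error(measure_apd90(cell_params(), stim_amp = 0), "no-capture")
  expect_error(step_cell(cell_default_state(), dt = 0.1))
  expect_error(cell_params("normal", remodeling_factors = c(g_na = 0.5)),
               "normal")
  expect_error(cell_params(iks_scale = -1))
  expect_error(calibrate_base_gks(600, tol = 1, n_beats = 20),
               "calibration failure")
})

test_that("cell parameters survive a JSON round trip", {
  p <- cell_params("border_zone", iks_scale = 1.4,
                   base_gks_calibration = 0.9)
  q <- cell_params_from_json(cell_params_to_json(p))
  expect_equal(p$remodeling_factors, q$remodeling_factors)
  expect_equal(p$iks_scale, q$iks_scale)
  expect_equal(p$base_gks_calibration, q$base_gks_calibration)
})

test_that("an APD sweep writes the documented delimited format", {
  f <- tempfile(fileext = ".tsv")
  sw <- apd_sweep(c(1, 2.25), n_beats = 20, file = f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(names(back), c("iks_scale", "pacing_cl", "apd90_ms"))
  expect_equal(back$apd90_ms, sw$apd90_ms)
  expect_gt(sw$apd90_ms[1], sw$apd90_ms[2])
})
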