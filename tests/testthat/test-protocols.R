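# Programmed stimulation: S1 trains, capture, ETS coupling search, XTS
# replay.

test_that("S1 drive-train times are the documented arithmetic sequences", {
  expect_equal(s1_train_times(600, 6), c(0, 600, 1200, 1800, 2400, 3000))
  expect_equal(tail(s1_train_times(350, 6), 1), 1750)
  expect_equal(s1_train_times(500, 1), 0)
  expect_error(s1_train_times(-1, 6))
})

test_that("pacing protocol validation enforces the XTS contract", {
  expect_error(pacing_protocol(mode = "XTS"), "XTS requires")
  expect_error(pacing_protocol(coupling_intervals = c(100, 100, 100, 100)))
  p <- pacing_protocol(2, 350, 4, c(180, 160), "XTS")
  expect_equal(p$coupling_intervals, c(180, 160))
})

test_that("capture detection separates recovered from refractory couplings and matches a 1-ms scan", {
  dom <- erp_scan_sheet()
  cfg <- fixture_sim_config(record_stride = 0, stim_amp = -40)
  setup <- vtgrad:::protocol_setup(dom, NULL, cfg, 2)
  train <- lapply(s1_train_times(300, 3), function(t0)
    vtgrad:::stim_at(setup, t0))
  base_mv <- vtgrad:::run_simulation_op(dom, NULL, setup$cfg, train,
                                        setup$op, record_stride = 0,
                                        duration = 612)
  trial <- function(cpl, step = TRUE) {
    t_stim <- 600 + cpl
    adv <- vtgrad:::run_simulation_op(dom, NULL, setup$cfg, list(),
                                      setup$op,
                                      initial_state = base_mv$final_state,
                                      t0 = 612, record_stride = 0,
                                      duration = t_stim - 612)
    mv <- vtgrad:::run_simulation_op(dom, NULL, setup$cfg,
                                     list(vtgrad:::stim_at(setup, t_stim)),
                                     setup$op,
                                     initial_state = adv$final_state,
                                     t0 = t_stim, record_stride = 0,
                                     duration = 220)
    detect_capture(mv, 1, 2, t_stim, setup$dist_mm)
  }
  # fully recovered and absolutely refractory couplings
  expect_true(trial(280))
  expect_false(trial(20))
  # exhaustive scan: capture is monotone above a threshold interval; the
  # ETS-discovered coupling matches the scan within one resolution step
  scan <- vapply(seq(100, 200, by = 4), trial, logical(1))
  expect_true(all(diff(scan) >= 0))  # monotone onset
  cmin_scan <- seq(100, 200, by = 4)[which(scan)[1]]
  erp <- local_erp_probe(dom, NULL, cfg, site = 2, bcl = 300, s1_count = 3,
                         resolution = 4, lb = 100)
  expect_lte(abs(erp - cmin_scan), 4)
})

test_that("ETS on a homogeneous gradient-free sheet does not induce VT", {
  # unmodified cells: the reentrant wavelength (~7 cm) far exceeds the
  # sheet, so no premature stimulus can start reentry without substrate
  dom <- fixture_sheet(48, 48, dx = 0.25)
  cfg <- fixture_sim_config(normal_gks_boost = 1, gcal_factor = 1,
                            record_stride = 2, stim_amp = -40)
  out <- run_ets(dom, NULL, cfg, site_index = 2, bcl = 400, s1_count = 3,
                 vt_check_ms = 700, vt_horizon_ms = 700)
  expect_false(out$vt_induced)
  expect_s3_class(out, "induction_outcome")
  # all three prematures were searched and captured
  expect_equal(length(out$protocol$coupling_intervals), 3)
  expect_true(all(out$captured))
})

test_that("ETS induces a >= 2-cycle VT on the figure-of-eight fixture", {
  out <- get_fig8_ets()
  expect_true(out$vt_induced)
  expect_gte(out$n_cycles, 2)
  expect_gt(out$post_stimulus_activity_ms, 2 * out$cycle_length)
})

test_that("XTS replay on the generating model reproduces the outcome bit-for-bit", {
  dom <- fixture_sheet(40, 40, dx = 0.25)
  cfg <- fixture_sim_config(record_stride = 2, stim_amp = -40)
  ets <- run_ets(dom, NULL, cfg, site_index = 2, bcl = 300, s1_count = 3,
                 max_premature = 2, vt_check_ms = 600, vt_horizon_ms = 600)
  expect_equal(length(ets$protocol$coupling_intervals), 2)
  xts <- run_xts(dom, NULL, cfg, ets$protocol, vt_horizon_ms = 600)
  expect_identical(xts$vt_induced, ets$vt_induced)
  expect_equal(unname(xts$captured), rep(TRUE, 2))
  # overlapping post-stimulus probe traces agree bitwise
  w0 <- ets$t_last_stimulus
  sel_e <- ets$movie$probe_t > w0 + 1e-6 & ets$movie$probe_t <= w0 + 500
  sel_x <- xts$movie$probe_t > w0 + 1e-6 & xts$movie$probe_t <= w0 + 500
  expect_identical(ets$movie$probe_vm[sel_e, ], xts$movie$probe_vm[sel_x, ])
})

test_that("XTS flags a premature stimulus that falls inside the local ERP", {
  dom <- fixture_sheet(40, 40, dx = 0.25)
  cfg <- fixture_sim_config(record_stride = 2, stim_amp = -40)
  proto <- pacing_protocol(2, 300, 3, c(40), "XTS")  # 40 ms << ERP
  out <- run_xts(dom, NULL, cfg, proto, vt_horizon_ms = 400)
  expect_false(out$captured[1])
  expect_false(out$vt_induced)
})
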