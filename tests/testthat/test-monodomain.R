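# Monodomain solver: equilibrium, scar handling, wavefront symmetry,
# anisotropy, convergence, determinism, ERP probe.

test_that("a resting sheet stays at rest without stimulus", {
  dom <- fixture_sheet(24, 24, dx = 0.5)
  cfg <- sim_config(duration = 500, record_stride = 0,
                    snapshot_nodes = rbind(c(2, 2), c(12, 12), c(23, 23)))
  mv <- run_simulation(dom, NULL, cfg, list())
  drift <- apply(mv$probe_vm, 2, function(v) max(abs(v - v[1])))
  expect_true(all(drift < 0.5))
})

test_that("scar is non-conducting: zero activation on scar, wave wraps around the bar", {
  tc <- matrix(0L, 40, 24)
  tc[20, 1:20] <- 2L  # bar with a right-hand gap
  dom <- tissue_domain(tc, dx = 0.25)
  cfg <- sim_config(duration = 120, record_stride = 2,
                    snapshot_nodes = rbind(c(18, 4), c(22, 4), c(22, 22)))
  stim <- list(stimulus(c(4, 4), t_on = 2, amplitude = -40, radius = 1))
  mv <- run_simulation(dom, NULL, cfg, stim)
  # scar nodes are excluded from the state and render NA in frames
  fr <- movie_frame(mv, length(mv$frame_t))
  expect_true(all(is.na(fr[20, 1:20])))
  expect_true(all(!is.na(fr[20, 21:24])))
  up <- function(p) {
    v <- mv$probe_vm[, p]
    mv$probe_t[which(v[-1] >= -40 & v[-length(v)] < -40)[1]]
  }
  # the node just beyond the bar activates much later than the node just
  # before it (the wave must round the gap), and later than the gap side
  expect_gt(up(2) - up(1), 20)
  expect_gt(up(2), up(3) - 5)
})

test_that("a point stimulus on an isotropic sheet gives a circular wavefront", {
  dom <- fixture_sheet(48, 48, dx = 0.5)
  cfg <- sim_config(duration = 120, D_l = 5e-4, D_t = 5e-4,
                    record_stride = 2)
  mv <- run_simulation(dom, NULL, cfg,
                       list(stimulus(c(24, 24), t_on = 2, amplitude = -40,
                                     radius = 1)))
  lat <- compute_lat(mv, c(0, 120))$lat
  reach <- function(dr, dc) {
    d <- 0
    while (TRUE) {
      r <- 24 + dr * (d + 1); c <- 24 + dc * (d + 1)
      if (r < 1 || r > 48 || c < 1 || c > 48 || is.na(lat[r, c]) ||
          lat[r, c] > 60) break
      d <- d + 1
    }
    d
  }
  ext_r <- (reach(1, 0) + reach(-1, 0)) / 2
  ext_c <- (reach(0, 1) + reach(0, -1)) / 2
  expect_lt(abs(ext_r / ext_c - 1), 0.05)
})

test_that("CV anisotropy matches sqrt(D_l/D_t) within 10%", {
  dom <- fixture_sheet(60, 60, dx = 0.25)  # fibers default to angle 0
  cfg <- sim_config(duration = 100, D_l = 1e-3, D_t = 1e-3 / 4,
                    record_stride = 0,
                    snapshot_nodes = rbind(c(46, 30), c(30, 46)))
  mv <- run_simulation(dom, NULL, cfg,
                       list(stimulus(c(30, 30), t_on = 2, amplitude = -40,
                                     radius = 0.75)))
  up <- vapply(1:2, function(p) {
    v <- mv$probe_vm[, p]
    mv$probe_t[which(v[-1] >= -40 & v[-length(v)] < -40)[1]]
  }, numeric(1))
  # same 4 mm distance along vs across fibers
  ratio <- up[2] / up[1]
  expect_lt(abs(ratio - 2) / 2, 0.10)
})

test_that("border-zone tissue conducts more slowly than normal tissue", {
  cv_n <- planar_cv(0.25, 1e-3)
  tc <- matrix(1L, 120, 12)  # all border zone
  dom <- tissue_domain(tc, dx = 0.25,
                       pacing_sites = cbind(117:119, rep(6, 3)))
  cfg <- sim_config(duration = 200, D_l = 1e-3, record_stride = 0,
                    snapshot_nodes = rbind(c(40, 6), c(80, 6)))
  stim <- list(stimulus(c(2, 6), t_on = 2, amplitude = -40,
                        nodes = cbind(rep(1:2, each = 12), rep(1:12, 2))))
  mv <- run_simulation(dom, NULL, cfg, stim)
  up <- vapply(1:2, function(p) {
    v <- mv$probe_vm[, p]
    mv$probe_t[which(v[-1] >= -40 & v[-length(v)] < -40)[1]]
  }, numeric(1))
  cv_bz <- (40 * 0.025) / ((up[2] - up[1]) / 1000)
  expect_lt(cv_bz, cv_n)
})

test_that("longitudinal CV is refinement-converged (< 3% change when dx is halved)", {
  cv1 <- planar_cv(0.125, 1e-3, dt_diffusion = 0.02, L_nodes = 240)
  cv2 <- planar_cv(0.0625, 1e-3, dt_reaction = 0.01, dt_diffusion = 0.01,
                   L_nodes = 480)
  expect_lt(abs(cv2 - cv1) / cv2, 0.03)
})

test_that("identical inputs give bitwise-identical probe traces", {
  dom <- fixture_sheet(30, 30, dx = 0.5)
  cfg <- sim_config(duration = 120, D_l = 5e-4, record_stride = 0,
                    snapshot_nodes = rbind(c(10, 10), c(25, 25)))
  st <- list(stimulus(c(15, 15), t_on = 4, amplitude = -40, radius = 1))
  a <- run_simulation(dom, NULL, cfg, st)
  b <- run_simulation(dom, NULL, cfg, st)
  expect_identical(a$probe_vm, b$probe_vm)
  expect_identical(a$final_state, b$final_state)
})

test_that("an ectopic beat dies out and the sheet returns to rest (no-flux conservation)", {
  dom <- fixture_sheet(30, 30, dx = 0.5)
  cfg <- fixture_sim_config(duration = 800, record_stride = 0,
                            snapshot_nodes = rbind(c(5, 5), c(15, 15),
                                                   c(28, 28)))
  mv <- run_simulation(dom, NULL, cfg,
                       list(stimulus(c(15, 15), t_on = 4, amplitude = -40,
                                     radius = 1)))
  last <- tail(mv$probe_vm, 1)
  expect_true(all(last < -75))
})

test_that("configuration errors are caught", {
  tc <- matrix(0L, 16, 16); tc[8, 8] <- 2L
  dom <- tissue_domain(tc, dx = 0.5)
  cfg <- sim_config(duration = 10)
  expect_error(run_simulation(dom, NULL, cfg,
                              list(stimulus(c(8, 8), t_on = 2,
                                            radius = 0))),
               "scar")
  expect_error(run_simulation(dom, NULL, cfg,
                              list(stimulus(c(2, 2), t_on = 50))),
               "window")
  expect_error(sim_config(dt_diffusion = 0.03, dt_reaction = 0.02))
  expect_error(sim_config(D_l = 1e-4, D_t = 1e-3))
})

test_that("the local ERP probe matches an exhaustive 1-ms scan in the single-cell limit", {
  dom <- tissue_domain(matrix(0L, 1, 1), dx = 0.5,
                       pacing_sites = cbind(1, 1))
  cfg <- fixture_sim_config(record_stride = 0, stim_amp = -52,
                            stim_duration = 1)
  erp <- local_erp_probe(dom, NULL, cfg, site = 1, bcl = 300, s1_count = 3,
                         resolution = 5, lb = 60)
  # oracle: exhaustive 1-ms scan of the same single cell
  m <- vtgrad:::config_mult(cfg)$normal
  st <- vtgrad:::cpp_cell_default_state()
  st <- vtgrad:::cpp_cell_steps(st, m, 0, 0.02, 50000L, 0L)$state
  for (b in 1:3) {
    st <- vtgrad:::cpp_cell_steps(st, m, -52, 0.02, 50L, 0L)$state
    if (b < 3) st <- vtgrad:::cpp_cell_steps(st, m, 0, 0.02, round(299 / 0.02), 0L)$state
  }
  base <- vtgrad:::cpp_cell_steps(st, m, 0, 0.02, round(9 / 0.02), 0L)$state # t=+10
  scan <- NA
  for (cpl in 60:300) {
    s2 <- vtgrad:::cpp_cell_steps(base, m, 0, 0.02, round((cpl - 10) / 0.02), 0L)$state
    tr <- vtgrad:::cpp_cell_steps(s2, m, -52, 0.02, 50L, 1L)
    tr2 <- vtgrad:::cpp_cell_steps(tr$state, m, 0, 0.02, round(14 / 0.02), 1L)
    vm <- c(tr$vm, tr2$vm)
    if (any(vm[-1] >= -40 & vm[-length(vm)] < -40)) { scan <- cpl; break }
  }
  expect_false(is.na(scan))
  expect_lte(abs(erp - scan), 5)
  expect_gte(erp, 60)
  expect_lte(erp, 300)
})
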