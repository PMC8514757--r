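# VT circuit analysis: LAT maps, reentry detection, isochrones, block
# lines, exit sites, pathway, circuit comparison.

# synthetic movie whose voltage is a square pulse after per-node
# activation times (possibly several per node)
fake_movie <- function(lat_list, shape, dx = 0.5, t_end = NULL,
                       stride = 1, apd = 80) {
  nr <- shape[1]; nc <- shape[2]
  nodes <- seq_len(nr * nc)
  if (is.null(t_end))
    t_end <- max(unlist(lat_list), 0, na.rm = TRUE) + apd + 20
  tt <- seq(0, t_end, by = stride)
  fr <- matrix(-85, length(nodes), length(tt))
  for (i in nodes) {
    for (a in lat_list[[i]]) {
      if (!is.finite(a)) next
      fr[i, tt >= a & tt <= a + apd] <- 10
    }
  }
  structure(list(frames = fr, frame_t = tt, probe_t = numeric(0),
                 probe_vm = matrix(0, 0, 0), nodes = nodes,
                 shape = shape, dx = dx, t0 = 0, t1 = t_end,
                 record_stride = stride),
            class = "voltage_movie")
}

test_that("LAT maps recover planar-wave activation times within one frame stride", {
  nr <- 10; nc <- 20
  v <- 0.5  # nodes per ms
  lat_true <- matrix(rep((0:(nc - 1)) / v + 5, each = nr), nr, nc)
  lat_list <- as.list(as.vector(lat_true))
  lat_list[[5]] <- numeric(0)  # one node never activates -> sentinel
  mv <- fake_movie(lat_list, c(nr, nc))
  lm <- compute_lat(mv, c(0, mv$t1))
  expect_true(is.na(lm$lat[5, 1]))
  err <- abs(lm$lat[-5] - lat_true[-5])
  expect_lt(max(err), 1)
  # a paced train: successive activations at one node spaced by the BCL
  mv2 <- fake_movie(list(c(10, 610, 1210)), c(1, 1), t_end = 1400)
  ev <- activation_events(mv2)
  expect_equal(diff(ev$t), c(600, 600), tolerance = 5)
})

test_that("a too-coarse frame stride is a resolution error", {
  mv <- fake_movie(list(10, 20), c(1, 2), stride = 5)
  expect_error(activation_events(mv), "resolution")
})

test_that("reentry detection rejects quiescence and single ectopic waves", {
  nr <- 8; nc <- 8
  quiet <- fake_movie(rep(list(numeric(0)), nr * nc), c(nr, nc),
                      t_end = 300)
  d0 <- detect_reentry(quiet, c(0, 300))
  expect_false(d0$reentry); expect_equal(d0$n_cycles, 0L)
  once <- fake_movie(as.list(runif(nr * nc, 5, 40)), c(nr, nc),
                     t_end = 400)
  d1 <- detect_reentry(once, c(0, 400))
  expect_false(d1$reentry); expect_equal(d1$n_cycles, 1L)
})

test_that("reentry detection is stimulus-blind (prepended beats never change the verdict)", {
  nr <- 8; nc <- 8
  base <- lapply(seq_len(nr * nc), function(i) 205 + (i %% 16) * 12.5 +
                   c(0, 200, 400))
  with_pacing <- lapply(base, function(a) c(30, a))  # stimulated beat at 30
  m1 <- fake_movie(base, c(nr, nc), t_end = 900, apd = 60)
  m2 <- fake_movie(with_pacing, c(nr, nc), t_end = 900, apd = 60)
  d1 <- detect_reentry(m1, c(200, 900))
  d2 <- detect_reentry(m2, c(200, 900))  # window starts after the beat
  expect_identical(d1$reentry, d2$reentry)
  expect_identical(d1$n_cycles, d2$n_cycles)
  expect_true(d1$reentry)
})

test_that("isochrone segmentation yields exactly 8 equal bins anchored at the exit", {
  lat <- matrix(seq(0, 199.999, length.out = 400), 20, 20)
  lab <- segment_isochrones(lat, exit_time = 200, cycle_length = 200)
  expect_true(all(sort(unique(as.vector(lab))) == 1:8))
  frac <- as.vector(table(lab)) / 400
  expect_true(all(abs(frac - 0.125) < 0.02))
  # all-at-once activation occupies one bin
  lab1 <- segment_isochrones(matrix(50, 5, 5), 200, 200)
  expect_equal(length(unique(as.vector(lab1))), 1L)
  # shifting the exit anchor by CL/8 rotates labels by exactly one bin
  lab2 <- segment_isochrones(lat, exit_time = 200 + 25, cycle_length = 200)
  expect_true(all(lab2 == ifelse(lab == 1, 8L, lab - 1L)))
  expect_error(segment_isochrones(lat, 100, 0), "positive")
})

test_that("planar and colliding waves produce no block lines", {
  lat_planar <- matrix(rep(seq(0, 95, length.out = 20), each = 20), 20, 20)
  expect_length(locate_block_lines(lat_planar, 300), 0)
  # two waves from opposite edges colliding mid-sheet
  x <- matrix(rep(0:19, each = 20), 20, 20)
  lat_collide <- pmin(x, 19 - x) * 5
  expect_length(locate_block_lines(lat_collide, 300), 0)
})

test_that("the figure-of-eight VT shows block lines, channel exits, and a closed pathway", {
  circ <- get_fig8_circuit()
  expect_true(circ$reentry)
  expect_gte(circ$n_cycles, 2)
  expect_gte(length(circ$block_lines), 1)
  # at least one block line lies along the channel's lateral boundaries
  dom <- fixture_fig8()
  ch_cols <- range(which(colSums(protected_bz_mask(dom)) > 0))
  near_channel <- vapply(circ$block_lines, function(bl)
    any((bl[, "c1"] >= ch_cols[1] - 3 & bl[, "c1"] <= ch_cols[2] + 3) |
          (bl[, "c2"] >= ch_cols[1] - 3 & bl[, "c2"] <= ch_cols[2] + 3)),
    logical(1))
  expect_true(any(near_channel))
  # exit sites: normal tissue adjacent to the border zone, fed causally
  expect_gte(nrow(circ$exit_sites), 1)
  for (i in seq_len(nrow(circ$exit_sites))) {
    p <- circ$exit_sites[i, ]
    expect_true(tissue_mask(dom, "normal")[p[1], p[2]])
  }
  # 8 isochrone bins partition the activated nodes
  iso <- circ$activation_map$isochrone_label
  expect_true(all(iso[!is.na(iso)] %in% 1:8))
  expect_equal(sum(!is.na(iso)),
               sum(!is.na(circ$activation_map$lat)))
  # pathway is a closed loop through the circuit
  expect_gt(nrow(circ$pathway), 10)
  expect_lte(sqrt(sum((circ$pathway[1, ] -
                         circ$pathway[nrow(circ$pathway), ])^2)), 2)
  expect_equal(circ$morphology, "double_loop")
})

test_that("the annulus circulation is detected with the analytic cycle-length oracle", {
  mv <- get_annulus_movie()
  det <- detect_reentry(mv, c(0, mv$t1))
  expect_true(det$reentry)
  expect_gte(det$n_cycles, 2)
  # anatomical oracle: mid-ring perimeter / measured planar CV
  cv <- planar_cv(0.25, 2.5e-4, extra = list(
    normal = c(g_ks = 6, g_cal = 0.5)))
  predicted <- 2 * pi * 9.5 / (cv / 100)  # mm / (mm/ms)
  expect_lt(abs(det$cycle_length - predicted) / predicted, 0.15)
})

test_that("circuit comparison is reflexive, threshold-sensitive, and chirality-aware", {
  a <- get_fig8_circuit()
  self <- compare_circuits(a, a)
  expect_true(self$pathway_match)
  expect_true(self$exit_site_match)
  expect_equal(self$common_channel_overlap, 1.0)
  expect_equal(self$distance_between_exit_sites, 0)
  # displaced exit site beyond the concordance radius
  b <- a
  b$exit_sites <- a$exit_sites + round(10 / a$dx)
  b$exit_sites[, 1] <- pmin(b$exit_sites[, 1], a$shape[1])
  b$exit_sites[, 2] <- pmin(b$exit_sites[, 2], a$shape[2])
  cmp <- compare_circuits(a, b, concordance_radius = 5)
  expect_true(cmp$pathway_match)
  expect_false(cmp$exit_site_match)
  # reversed traversal sense on the same channel is not a pathway match
  r <- a
  r$pathway <- a$pathway[rev(seq_len(nrow(a$pathway))), ]
  cmpr <- compare_circuits(a, r)
  expect_false(cmpr$pathway_match)
  expect_gte(cmpr$common_channel_overlap, 0.99)
  # symmetry of the comparison
  cmp_ab <- compare_circuits(a, b)
  cmp_ba <- compare_circuits(b, a)
  expect_identical(cmp_ab$pathway_match, cmp_ba$pathway_match)
  expect_identical(cmp_ab$exit_site_match, cmp_ba$exit_site_match)
  expect_equal(cmp_ab$distance_between_exit_sites,
               cmp_ba$distance_between_exit_sites)
})

test_that("every reentrant pathway encircles a block line or scar component", {
  circ <- get_fig8_circuit()
  dom <- fixture_fig8()
  scar_lab <- vtgrad:::cpp_label_components(tissue_mask(dom, "scar"), 8L)
  enc <- 0
  for (k in seq_len(max(scar_lab))) {
    cen <- colMeans(which(scar_lab == k, arr.ind = TRUE))
    enc <- enc + vtgrad:::point_in_polygon(cen, circ$pathway)
  }
  expect_gte(enc + length(circ$block_lines), 1)
  expect_true(enc >= 1 || length(circ$block_lines) >= 1)
})

test_that("activation maps export as text and VTK", {
  circ <- get_fig8_circuit()
  stem <- file.path(tempdir(), "vtmap")
  write_activation_map(circ, stem)
  expect_true(file.exists(paste0(stem, ".lat.txt")))
  lat_back <- as.matrix(read.table(paste0(stem, ".lat.txt")))
  expect_equal(dim(lat_back), circ$shape)
  vtk <- readLines(paste0(stem, ".vtk"))
  expect_equal(vtk[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("SCALARS isochrone", vtk)))
})
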