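# Synthetic infarct substrate generator: determinism, fraction targets,
# channels, localization, serialization.

test_that("generation is deterministic for a fixed seed", {
  p <- substrate_params(nr = 96, nc = 96, rng_seed = 7)
  a <- generate_substrate(p)
  b <- generate_substrate(p)
  expect_identical(a$tissue_class, b$tissue_class)
  expect_identical(a$pacing_sites, b$pacing_sites)
})

test_that("zero scar target yields an all-normal sheet", {
  p <- substrate_params(nr = 48, nc = 48, target_scar_fraction = 0,
                        target_bz_fraction = 0, n_channels = 0)
  d <- suppressWarnings(generate_substrate(p))  # small-grid site spacing
  expect_true(all(d$tissue_class == 0L))
  s <- summarize_substrate(d)
  expect_equal(s$scar_fraction, 0)
  expect_equal(s$bz_fraction, 0)
  expect_equal(s$n_scar_components, 0L)
  expect_equal(s$n_channels, 0L)
})

test_that("summary arithmetic is exact on a hand-built toy grid", {
  tc <- matrix(0L, 10, 10)
  tc[3:6, 4:6] <- 2L  # 12 scar nodes
  d <- tissue_domain(tc, dx = 1)
  s <- summarize_substrate(d)
  expect_equal(s$scar_fraction, 0.12)
  expect_equal(s$n_scar_components, 1L)
})

test_that("channel detection finds a known corridor and rejects a solid bar", {
  tc <- matrix(0L, 24, 24)
  tc[9:14, ] <- 2L
  tc[9:14, 11:13] <- 1L   # conducting gap through the bar
  d <- tissue_domain(tc, dx = 1)
  d$params <- substrate_params(nr = 24, nc = 24, channel_min_width = 2)
  expect_gte(summarize_substrate(d)$n_channels, 1L)

  solid <- matrix(0L, 24, 24)
  solid[9:14, ] <- 2L
  d2 <- tissue_domain(solid, dx = 1)
  d2$params <- substrate_params(nr = 24, nc = 24, channel_min_width = 2)
  expect_equal(summarize_substrate(d2)$n_channels, 0L)
})

test_that("generated substrates hit the fraction targets, localize apically, and validate", {
  fr <- t(vapply(1:10, function(k) {
    d <- generate_substrate(substrate_params(rng_seed = k))
    validate_domain(d)
    s <- summarize_substrate(d)
    expect_gte(s$n_channels, 1L)
    scar <- tissue_mask(d, "scar")
    centroid_ab <- (mean(row(scar)[scar]) - 1) / (nrow(scar) - 1)
    expect_lt(abs(centroid_ab - d$params$scar_centroid_ab), 0.15)
    c(s$scar_fraction, s$bz_fraction)
  }, numeric(2)))
  # per-substrate within 20% relative of target, means inside the
  # patient-cohort band (12.6 +/- 5.0 and 6.8 +/- 1.9 percent)
  expect_true(all(abs(fr[, 1] - 0.126) <= 0.2 * 0.126))
  expect_true(all(abs(fr[, 2] - 0.068) <= 0.2 * 0.068))
  expect_lt(abs(mean(fr[, 1]) - 0.126), 0.05)
  expect_lt(abs(mean(fr[, 2]) - 0.068), 0.019)
})

test_that("channel connectivity: a conducting path crosses the scar band (BFS oracle)", {
  d <- generate_substrate(substrate_params(rng_seed = 3))
  scar <- tissue_mask(d, "scar")
  rows <- range(which(rowSums(scar) > 0))
  cols <- range(which(colSums(scar) > 0))
  # independent BFS over conducting nodes restricted to the scar's column
  # span: some path must connect the rows above and below the scar
  cond <- tissue_mask(d, "conducting")
  sub <- cond[, cols[1]:cols[2]]
  nr <- nrow(sub); nc <- ncol(sub)
  start <- which(sub[1, ])
  reach <- matrix(FALSE, nr, nc)
  reach[1, start] <- TRUE
  frontier <- cbind(1L, start)
  while (nrow(frontier)) {
    nxt <- NULL
    for (d8 in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, 1),
                    c(1, -1), c(-1, 1), c(-1, -1))) {
      cand <- cbind(frontier[, 1] + d8[1], frontier[, 2] + d8[2])
      ok <- cand[, 1] >= 1 & cand[, 1] <= nr & cand[, 2] >= 1 &
        cand[, 2] <= nc
      cand <- cand[ok, , drop = FALSE]
      ok2 <- sub[cand] & !reach[cand]
      reach[cand[ok2, , drop = FALSE]] <- TRUE
      nxt <- rbind(nxt, cand[ok2, , drop = FALSE])
    }
    frontier <- unique(nxt)
    if (is.null(frontier)) frontier <- matrix(0L, 0, 2)
  }
  expect_true(any(reach[nr, ]))
})

test_that("pacing sites are non-scar, apical, and mutually spaced", {
  d <- generate_substrate(substrate_params(rng_seed = 11))
  ps <- d$pacing_sites
  expect_gte(nrow(ps), 3)
  for (i in seq_len(nrow(ps)))
    expect_false(tissue_mask(d, "scar")[ps[i, 1], ps[i, 2]])
  expect_true(all(ps[, 1] >= 0.85 * nrow(d$tissue_class)))
  dmin <- min(dist(ps * d$params$dx))
  expect_gte(dmin, d$params$pacing_min_dist)
})

test_that("substrates survive a write/read round trip", {
  d <- generate_substrate(substrate_params(nr = 64, nc = 64, rng_seed = 5))
  stem <- file.path(tempdir(), "subst")
  write_substrate(d, stem)
  e <- read_substrate(stem)
  expect_identical(d$tissue_class, e$tissue_class)
  expect_equal(d$fiber_angle, e$fiber_angle, tolerance = 1e-6)
  expect_equal(unname(d$pacing_sites[, 1:2]), unname(e$pacing_sites[, 1:2]))
})

test_that("a grid too small for the requested channel errors", {
  expect_error(generate_substrate(substrate_params(nr = 8, nc = 8,
                                                   channel_min_width = 2)),
               "too small")
})
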