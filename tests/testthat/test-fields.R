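# Coordinate fields: geodesic apicobasal distance, transmural Laplace
# solution, I_Ks scaling field.

test_that("geodesic field is analytic on an obstacle-free sheet", {
  d <- fixture_sheet(20, 12, dx = 0.5)
  u <- geodesic_ab_field(d)
  expect_equal(u, matrix(rep((0:19) / 19, 12), 20, 12),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(u[1, ] == 0))
})

test_that("geodesic field matches the brute-force shortest-path oracle on random obstacle grids", {
  for (seed in 1:10) {
    set.seed(seed)
    nr <- sample(10:30, 1); nc <- sample(10:30, 1)
    cond <- matrix(runif(nr * nc) > 0.25, nr, nc)
    cond[1, ] <- TRUE  # conducting base edge
    d <- tissue_domain(matrix(ifelse(cond, 0L, 2L), nr, nc), dx = 0.5)
    u <- geodesic_ab_field(d)
    oracle <- igraph_geodesic_oracle(cond, 0.5)
    oracle[is.infinite(oracle)] <- NA
    mx <- max(oracle, na.rm = TRUE)
    expect_equal(u[!is.na(oracle)], oracle[!is.na(oracle)] / mx,
                 tolerance = 1e-12)
  }
})

test_that("a detour around a scar gap equals the around-the-gap path length", {
  tc <- matrix(0L, 15, 15)
  tc[8, ] <- 2L
  tc[8, 7] <- 0L  # one-node gap
  d <- tissue_domain(tc, dx = 1)
  u <- geodesic_ab_field(d)
  oracle <- igraph_geodesic_oracle(tissue_mask(d, "conducting"), 1)
  expect_equal(u, oracle / max(oracle, na.rm = TRUE), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("geodesic field errors without a conducting base edge", {
  tc <- matrix(0L, 10, 10)
  tc[1, ] <- 2L
  expect_error(geodesic_ab_field(tissue_domain(tc)), "base edge")
})

test_that("Laplace field is linear on a rectangle and zero under zero boundaries", {
  d <- fixture_sheet(16, 25, dx = 0.5)
  u <- laplace_tm_field(d)
  expect_lt(max(abs(u - matrix(rep((0:24) / 24, each = 16), 16, 25))), 1e-6)
  u0 <- laplace_tm_field(d, endo_value = 0, epi_value = 0)
  expect_true(all(u0 == 0))
})

test_that("Laplace field with a scar hole matches a dense direct solve", {
  nr <- 24; nc <- 28
  tc <- matrix(0L, nr, nc)
  tc[8:14, 10:18] <- 2L
  d <- tissue_domain(tc, dx = 0.5)
  u <- laplace_tm_field(d)
  dense <- laplace_dense_oracle(d)
  expect_lt(max(abs(u - dense), na.rm = TRUE), 1e-8)
  # maximum principle: interior extrema stay inside (0, 1)
  interior <- tissue_mask(d, "conducting") & !(col(tc) %in% c(1, nc))
  expect_true(all(u[interior] > 0 & u[interior] < 1))
})

test_that("the I_Ks scaling field hits the documented extremes per variant", {
  d <- fixture_sheet(12, 12)
  f <- coordinate_fields(d, "ab_tm")
  # basal endocardium (1,1) -> 1.0; apical epicardium (12,12) -> 2.25
  expect_equal(f$iks_scale_field[1, 1], 1.0)
  expect_equal(f$iks_scale_field[12, 12], 2.25)
  fab <- coordinate_fields(d, "ab")
  expect_equal(range(fab$iks_scale_field), c(1, 1.5))
  expect_equal(fab$iks_scale_field[12, 1], 1.5)
  ftm <- coordinate_fields(d, "tm")
  expect_equal(range(ftm$iks_scale_field), c(1, 1.5))
  fb <- coordinate_fields(d, "baseline")
  expect_true(all(fb$iks_scale_field == 1))
})

test_that("border-zone nodes keep unscaled I_Ks unless asked otherwise", {
  tc <- matrix(0L, 12, 12)
  tc[6, 6] <- 1L
  d <- tissue_domain(tc)
  f <- coordinate_fields(d, "ab_tm")
  expect_equal(f$iks_scale_field[6, 6], 1.0)
  fbz <- coordinate_fields(d, "ab_tm", bz_gradient = TRUE)
  expect_gt(fbz$iks_scale_field[6, 6], 1.0)
})

test_that("an unreachable normal region triggers a field-construction error", {
  tc <- matrix(0L, 12, 12)
  tc[6, ] <- 2L  # full scar bar disconnects the apical half
  d <- tissue_domain(tc)
  u_ab <- geodesic_ab_field(d)
  expect_gt(attr(u_ab, "n_unreachable"), 0)
  u_tm <- laplace_tm_field(d)
  expect_error(build_iks_scale_field(u_ab, u_tm, "ab", d),
               "field-construction")
})
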