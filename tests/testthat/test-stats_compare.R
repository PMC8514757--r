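# Fisher's exact test from first principles and the cross-variant match
# matrices.

hypergeom_oracle <- function(tb) {
  # independent enumeration via R's hypergeometric density
  r1 <- sum(tb[1, ]); c1 <- sum(tb[, 1]); n <- sum(tb)
  k <- max(0, c1 - (n - r1)):min(r1, c1)
  d <- dhyper(k, r1, n - r1, c1)
  dobs <- dhyper(tb[1, 1], r1, n - r1, c1)
  sum(d[d <= dobs * (1 + 1e-7)])
}

test_that("fisher_exact reproduces frozen enumeration values", {
  expect_equal(fisher_exact(rbind(c(3, 1), c(1, 3))), 0.4857142857142857,
               tolerance = 1e-12)
  expect_equal(fisher_exact(rbind(c(0, 5), c(0, 7))), 1.0)
  expect_equal(fisher_exact(rbind(c(10, 0), c(0, 10))), 2 / choose(20, 10),
               tolerance = 1e-12)
})

test_that("fisher_exact equals the enumeration oracle on all small tables and random larger ones", {
  for (n in 1:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      tb <- rbind(c(a, b), c(cc, n - a - b - cc))
      expect_equal(fisher_exact(tb), hypergeom_oracle(tb),
                   tolerance = 1e-12)
    }
  }
  set.seed(1)
  for (k in 1:200) {
    tb <- matrix(rpois(4, 6), 2, 2)
    if (sum(tb) == 0) next
    expect_equal(fisher_exact(tb), hypergeom_oracle(tb), tolerance = 1e-12)
    expect_equal(fisher_exact(tb), fisher.test(tb)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("p lies in (0,1] and is invariant under simultaneous row and column swaps", {
  set.seed(2)
  for (k in 1:50) {
    tb <- matrix(rpois(4, 4), 2, 2)
    if (sum(tb) == 0) next
    p <- fisher_exact(tb)
    expect_gt(p, 0)
    expect_lte(p, 1 + 1e-12)
    expect_equal(p, fisher_exact(tb[2:1, 2:1]), tolerance = 1e-12)
  }
})

test_that("degenerate tables are rejected", {
  expect_error(fisher_exact(matrix(0, 2, 2)), "all-zero")
  expect_error(fisher_exact(rbind(c(1.5, 1), c(1, 1))))
  expect_error(fisher_exact(rbind(c(-1, 1), c(1, 1))))
})

test_that("match tables follow the published counting convention", {
  # 3 of 6 matches vs 2 of 7 matches -> [[3,3],[2,5]]
  a <- c(rep("match", 3), rep("no_match", 3))
  b <- c(rep("match", 2), rep("no_match", 5))
  expect_equal(unname(match_table(a, b)), rbind(c(3, 3), c(2, 5)),
               ignore_attr = TRUE)
})

test_that("build_match_matrix assembles per-VT states and 2x2 tables per contrast", {
  man <- rbind(
    data.frame(vt_id = sprintf("VT%d", 1:6), variant = "baseline",
               mode = "ETS", induced = TRUE, pathway_match = NA,
               exit_site_match = NA),
    data.frame(vt_id = sprintf("VT%d", 1:6), variant = "ab_tm",
               mode = "ETS", induced = rep(c(TRUE, FALSE), c(5, 1)),
               pathway_match = c(TRUE, TRUE, TRUE, FALSE, FALSE, NA),
               exit_site_match = c(TRUE, TRUE, TRUE, FALSE, FALSE, NA)),
    data.frame(vt_id = sprintf("VT%d", 1:6), variant = "ab_tm",
               mode = "XTS", induced = TRUE,
               pathway_match = rep(c(TRUE, FALSE), c(2, 4)),
               exit_site_match = rep(c(TRUE, FALSE), c(2, 4))))
  s <- build_match_matrix(man, contrasts = list(c("baseline", "ab_tm")))
  ct <- s[["baseline_vs_ab_tm"]]
  expect_equal(unname(ct$tables$exit_site), rbind(c(3, 2), c(2, 4)))
  expect_equal(unname(ct$tables$inducibility), rbind(c(6, 0), c(11, 1)))
  expect_equal(nrow(ct$states), 12)  # 6 ETS + 6 XTS rows for ab_tm
  expect_true(all(ct$states[, "pathway"] %in%
                    c("match", "no_match", "no_vt")))
  for (p in ct$p_values) if (!is.na(p)) {
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("all-matching manifests give p = 1 and duplicate identifiers error", {
  man <- data.frame(vt_id = c("VT1", "VT1"), variant = c("baseline", "ab_tm"),
                    mode = "ETS", induced = TRUE, pathway_match = TRUE,
                    exit_site_match = TRUE)
  s <- build_match_matrix(man, contrasts = list(c("baseline", "ab_tm")))
  expect_equal(s[["baseline_vs_ab_tm"]]$p_values$pathway, 1)
  dup <- rbind(man, man[2, ])
  expect_error(build_match_matrix(dup, contrasts = list(c("baseline", "ab_tm"))),
               "duplicate")
})
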