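# Expensive simulated fixtures are computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# figure-of-eight VT induced by the ETS protocol on the shipped fixture
get_fig8_ets <- function() {
  cached("fig8_ets", {
    dom <- fixture_fig8()
    cfg <- fixture_sim_config(record_stride = 2, stim_amp = -40)
    run_ets(dom, NULL, cfg, site_index = 2, bcl = 350, s1_count = 4,
            vt_check_ms = 1500, vt_horizon_ms = 1500)
  })
}

get_fig8_circuit <- function() {
  cached("fig8_circuit", analyze_vt(get_fig8_ets(), fixture_fig8()))
}

# anatomical reentry circulating the scar-annulus ring corridor
get_annulus_movie <- function() {
  cached("annulus_movie", {
    dom <- fixture_annulus()
    cfg <- fixture_sim_config(duration = 1000, record_stride = 2)
    cen <- c((nrow(dom$tissue_class) + 1) / 2,
             (ncol(dom$tissue_class) + 1) / 2)
    age <- annulus_age_ramp(96, 96, cen)
    S0 <- crossfield_state(dom, cfg, age)
    run_simulation(dom, NULL, cfg, list(), initial_state = S0)
  })
}

# small sheet used for capture / ERP scans
erp_scan_sheet <- function() fixture_sheet(48, 20, dx = 0.25)

# planar conduction velocity measured on a thin strip (cm/s)
planar_cv <- function(dx, D_l, dt_diffusion = 0.1, L_nodes = 120,
                      W_nodes = 12, extra = NULL, dt_reaction = 0.02) {
  dom <- fixture_sheet(L_nodes, W_nodes, dx = dx)
  r1 <- round(L_nodes / 3); r2 <- round(2 * L_nodes / 3)
  cfg <- sim_config(duration = 140, D_l = D_l, dt_diffusion = dt_diffusion,
                    dt_reaction = dt_reaction, record_stride = 0,
                    snapshot_nodes = rbind(c(r1, W_nodes %/% 2),
                                           c(r2, W_nodes %/% 2)),
                    extra_conductance_mult = extra)
  depth <- max(2, round(0.5 / dx))  # ~0.5 mm stimulated band
  stim <- list(stimulus(c(2, W_nodes %/% 2), t_on = 2, amplitude = -40,
                        nodes = cbind(rep(seq_len(depth), each = W_nodes),
                                      rep(seq_len(W_nodes), depth))))
  mv <- run_simulation(dom, NULL, cfg, stim)
  up <- vapply(1:2, function(p) {
    v <- mv$probe_vm[, p]; t <- mv$probe_t
    i <- which(v[-1] >= -40 & v[-length(v)] < -40)[1]
    t[i] + (t[i + 1] - t[i]) * (-40 - v[i]) / (v[i + 1] - v[i])
  }, numeric(1))
  ((r2 - r1) * dx / 10) / ((up[2] - up[1]) / 1000)  # cm/s
}


igraph_geodesic_oracle <- function(cond, dx) {
  # independent shortest-path oracle: explicit 8-connected graph
  nr <- nrow(cond); nc <- ncol(cond)
  id <- matrix(seq_len(nr * nc), nr, nc)
  edges <- NULL; w <- NULL
  for (d in list(c(1, 0, 1), c(0, 1, 1), c(1, 1, sqrt(2)),
                 c(1, -1, sqrt(2)))) {
    r1 <- rep(seq_len(nr), nc); c1 <- rep(seq_len(nc), each = nr)
    r2 <- r1 + d[1]; c2 <- c1 + d[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ok[ok] <- cond[cbind(r1[ok], c1[ok])] & cond[cbind(r2[ok], c2[ok])]
    edges <- rbind(edges, cbind(id[cbind(r1[ok], c1[ok])],
                                id[cbind(r2[ok], c2[ok])]))
    w <- c(w, rep(d[3] * dx, sum(ok)))
  }
  g <- igraph::graph_from_edgelist(apply(edges, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- w
  src <- as.character(id[1, ][cond[1, ]])
  dmat <- igraph::distances(g, v = src)
  d_or <- matrix(NA_real_, nr, nc)
  nodes <- as.integer(igraph::V(g)$name)
  d_or[nodes] <- apply(dmat, 2, min)
  d_or[!cond] <- NA
  d_or
}


# independent dense direct-solve oracle for the transmural Laplace problem
# (loops, full matrix, base solve())
laplace_dense_oracle <- function(domain) {
  cond <- tissue_mask(domain, "conducting")
  nr <- nrow(cond); nc <- ncol(cond)
  idx <- matrix(NA_integer_, nr, nc)
  unknown <- cond & !(col(cond) %in% c(1, nc))
  idx[unknown] <- seq_len(sum(unknown))
  n <- sum(unknown)
  A <- matrix(0, n, n); b <- numeric(n)
  for (r in 1:nr) for (c in 1:nc) {
    if (!isTRUE(unknown[r, c])) next
    i <- idx[r, c]
    for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      r2 <- r + dd[1]; c2 <- c + dd[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!cond[r2, c2]) next
      A[i, i] <- A[i, i] + 1
      if (!is.na(idx[r2, c2])) A[i, idx[r2, c2]] <- A[i, idx[r2, c2]] - 1
      else b[i] <- b[i] + (c2 == nc)  # epi edge Dirichlet value 1
    }
  }
  sol <- solve(A, b)
  dense <- matrix(NA_real_, nr, nc)
  dense[unknown] <- sol
  dense[, 1][cond[, 1]] <- 0
  dense[, nc][cond[, nc]] <- 1
  dense
}
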