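# Anisotropic monodomain reaction-diffusion solver on the tissue grid:
# operator splitting between the ionic reaction step (cell model at
# dt_reaction) and a 9-point anisotropic finite-difference diffusion step
# (dt_diffusion). Scar and outside nodes carry zero conductivity; edge-wise
# harmonic-mean conductivities make scar interfaces flux-free.

#' Simulation configuration
#'
#' @param duration Simulated time (ms).
#' @param dt_reaction Reaction (cell-model) step (ms), at most 0.05.
#' @param dt_diffusion Diffusion step (ms); an integer multiple of
#'   `dt_reaction`.
#' @param D_l,D_t Longitudinal/transverse diffusion coefficients (cm^2/ms;
#'   conductivity over surface-to-volume ratio times capacitance). Defaults
#'   give a longitudinal conduction velocity of about 60 cm/s and
#'   transverse about 24 cm/s in normal tissue at dx = 0.25 mm.
#' @param bz_conduction_factor Multiplier (< 1) on the transverse
#'   conductivity of border-zone tissue (slow-conduction substrate).
#' @param record_stride Time between saved voltage frames (ms); 0 disables
#'   frame recording (probe traces are always dense).
#' @param snapshot_nodes Optional matrix of 1-based `(row, col)` probe
#'   nodes.
#' @param stim_radius Stimulus disc radius (mm).
#' @param stim_duration Stimulus pulse duration (ms).
#' @param stim_amp Stimulus amplitude (uA/uF, cathodal negative). `NULL`
#'   means "2x diastolic threshold", resolved once per configuration by
#'   [find_diastolic_threshold()] when a protocol starts.
#' @param base_gks_calibration Baseline I_Ks calibration multiplier applied
#'   to every cell (see [calibrate_base_gks()]).
#' @param bz_remodeling Border-zone conductance multipliers.
#' @param extra_conductance_mult Optional named list
#'   (`normal`, `border_zone`) of extra conductance multipliers (names
#'   among `g_na`, `g_cal`, `g_kr`, `g_ks`) applied on top of the tissue
#'   class; used by reduced desk-scale fixtures.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(duration = 1000, dt_reaction = 0.02,
                       dt_diffusion = 0.1, D_l = 0.001, D_t = NULL,
                       bz_conduction_factor = 0.25, record_stride = 2,
                       snapshot_nodes = NULL, stim_radius = 1,
                       stim_duration = 2, stim_amp = -80,
                       base_gks_calibration = 1,
                       bz_remodeling = bz_remodeling_defaults(),
                       extra_conductance_mult = NULL) {
  if (is.null(D_t)) D_t <- D_l / 6.25
  sub <- dt_diffusion / dt_reaction
  stopifnot(dt_reaction > 0, dt_reaction <= 0.05,
            abs(sub - round(sub)) < 1e-9, D_t <= D_l, D_t > 0,
            bz_conduction_factor > 0, bz_conduction_factor <= 1)
  structure(list(duration = duration, dt_reaction = dt_reaction,
                 dt_diffusion = dt_diffusion, D_l = D_l, D_t = D_t,
                 bz_conduction_factor = bz_conduction_factor,
                 record_stride = record_stride,
                 snapshot_nodes = snapshot_nodes,
                 stim_radius = stim_radius, stim_duration = stim_duration,
                 stim_amp = stim_amp,
                 base_gks_calibration = base_gks_calibration,
                 bz_remodeling = bz_remodeling,
                 extra_conductance_mult = extra_conductance_mult),
            class = "sim_config")
}

#' Stimulus definition
#'
#' A cathodal current pulse injected in a disc of conducting nodes around
#' a site.
#'
#' @param site 1-based `(row, col)` center node.
#' @param t_on Onset (ms, absolute simulation time).
#' @param duration Pulse duration (ms).
#' @param amplitude Current (uA/uF); negative = depolarizing.
#' @param radius Disc radius (mm).
#' @param nodes Optional explicit matrix of 1-based `(row, col)` nodes
#'   (e.g. a full-edge line stimulus); overrides the disc.
#' @return Object of class `stimulus`.
#' @export
stimulus <- function(site, t_on, duration = 2, amplitude = -80,
                     radius = 1, nodes = NULL) {
  structure(list(site = as.integer(site), t_on = t_on, duration = duration,
                 amplitude = amplitude, radius = radius, nodes = nodes),
            class = "stimulus")
}

stim_nodes <- function(domain, stim) {
  cond <- tissue_mask(domain, "conducting")
  if (!is.null(stim$nodes)) {
    nd <- matrix(as.integer(stim$nodes), ncol = 2)
    keep <- cond[nd]
    if (!any(keep)) stop("configuration error: stimulus entirely on scar/outside")
    return(nd[keep, , drop = FALSE])
  }
  nr <- nrow(cond); nc <- ncol(cond)
  rad <- max(stim$radius / domain$dx, 0)
  r0 <- stim$site[1]; c0 <- stim$site[2]
  rs <- max(1, floor(r0 - rad)):min(nr, ceiling(r0 + rad))
  cs <- max(1, floor(c0 - rad)):min(nc, ceiling(c0 + rad))
  sel <- expand.grid(row = rs, col = cs)
  d <- sqrt((sel$row - r0)^2 + (sel$col - c0)^2)
  sel <- sel[d <= rad + 1e-9, , drop = FALSE]
  keep <- cond[cbind(sel$row, sel$col)]
  if (!any(keep)) stop("configuration error: stimulus entirely on scar/outside")
  if (!cond[r0, c0]) stop("configuration error: stimulus centered on scar")
  as.matrix(sel[keep, , drop = FALSE])
}

# 12-element multiplier vectors per tissue class under a sim_config
config_mult <- function(config) {
  nm <- cell_params("normal",
                    base_gks_calibration = config$base_gks_calibration)
  bz <- cell_params("border_zone",
                    base_gks_calibration = config$base_gks_calibration,
                    remodeling_factors = config$bz_remodeling)
  mv <- list(normal = mult_vector(nm), border_zone = mult_vector(bz))
  ex <- config$extra_conductance_mult
  if (!is.null(ex)) {
    slot <- c(g_na = 1, g_cal = 2, g_kr = 3, g_ks = 4)
    for (cls in names(ex))
      for (cn in names(ex[[cls]]))
        mv[[cls]][slot[[cn]]] <- mv[[cls]][slot[[cn]]] * ex[[cls]][[cn]]
  }
  mv
}

#' Assemble the anisotropic diffusion operator
#'
#' 9-point finite-difference discretization of `div(D grad V)` with the
#' local diffusion tensor built from the fiber angle and `(D_l, D_t)`.
#' Direct-neighbor weights use edge-wise harmonic means (zero at scar
#' interfaces, hence no-flux); mixed-derivative terms are dropped within
#' one node of a non-conducting node or the grid boundary so every row of
#' the operator sums to zero (charge conservation).
#'
#' @param domain A `tissue_domain`.
#' @param config A [sim_config()].
#' @return List with the CSR arrays (`p`, `j`, `x`), the compact node
#'   index (`nodes`, column-major indices of conducting nodes), and the
#'   grid shape.
#' @export
build_diffusion_operator <- function(domain, config) {
  cond <- tissue_mask(domain, "conducting")
  bzm <- tissue_mask(domain, "border_zone")
  nr <- nrow(cond); nc <- ncol(cond)
  h <- domain$dx / 10  # cm
  th <- domain$fiber_angle
  Dl <- matrix(config$D_l, nr, nc)
  Dt <- matrix(config$D_t, nr, nc)
  Dt[bzm] <- Dt[bzm] * config$bz_conduction_factor
  # fiber angle measured from the apicobasal (row) axis
  ct <- cos(th); st <- sin(th)
  Drr <- Dl * ct^2 + Dt * st^2
  Dcc <- Dl * st^2 + Dt * ct^2
  Drc <- (Dl - Dt) * ct * st
  Drr[!cond] <- 0; Dcc[!cond] <- 0; Drc[!cond] <- 0
  # cross terms only where the full 8-neighborhood conducts
  inner <- matrix(FALSE, nr, nc)
  if (nr > 2 && nc > 2) {
    ok <- cond
    all8 <- ok[2:(nr - 1), 2:(nc - 1)]
    for (dr in -1:1) for (dc in -1:1)
      all8 <- all8 & ok[2:(nr - 1) + dr, 2:(nc - 1) + dc]
    inner[2:(nr - 1), 2:(nc - 1)] <- all8
  }
  Drc[!inner] <- 0

  idx <- matrix(NA_integer_, nr, nc)
  nodes <- which(cond)
  idx[nodes] <- seq_along(nodes)
  n <- length(nodes)
  rr <- ((nodes - 1) %% nr) + 1
  cc <- ((nodes - 1) %/% nr) + 1
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)

  add <- function(i, j, w) {
    keep <- w != 0 & !is.na(j)
    ii <<- c(ii, i[keep]); jj <<- c(jj, j[keep]); xx <<- c(xx, w[keep])
  }
  harm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  h2 <- h * h
  # direct neighbors
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    r2 <- rr + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ok[ok] <- cond[cbind(r2[ok], c2[ok])]
    Dhere <- if (d[1] != 0) Drr else Dcc
    w <- numeric(n)
    w[ok] <- harm(Dhere[cbind(rr[ok], cc[ok])],
                  Dhere[cbind(r2[ok], c2[ok])]) / h2
    add(seq_len(n), ifelse(ok, idx[cbind(pmin(pmax(r2, 1), nr),
                                         pmin(pmax(c2, 1), nc))], NA), w)
    add(seq_len(n), seq_len(n), -w)
  }
  # mixed terms: d/dr(Drc dV/dc) + d/dc(Drc dV/dr)
  gDrc <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- numeric(length(r))
    out[ok] <- Drc[cbind(r[ok], c[ok])]
    out
  }
  q <- 1 / (4 * h2)
  D_rp <- gDrc(rr + 1, cc); D_rm <- gDrc(rr - 1, cc)
  D_cp <- gDrc(rr, cc + 1); D_cm <- gDrc(rr, cc - 1)
  at <- function(dr, dc) {
    r2 <- rr + dr; c2 <- cc + dc
    ifelse(r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc,
           idx[cbind(pmin(pmax(r2, 1), nr), pmin(pmax(c2, 1), nc))],
           NA_integer_)
  }
  add(seq_len(n), at(1, 1), q * (D_rp + D_cp))
  add(seq_len(n), at(-1, -1), q * (D_rm + D_cm))
  add(seq_len(n), at(1, -1), -q * (D_rp + D_cm))
  add(seq_len(n), at(-1, 1), -q * (D_rm + D_cp))

  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Mr <- as(M, "RsparseMatrix")
  list(p = Mr@p, j = Mr@j, x = Mr@x, nodes = nodes, shape = c(nr, nc))
}

# per-node 12-row multiplier matrix from tissue class + I_Ks field
node_mult_matrix <- function(domain, fields, config, op) {
  mv <- config_mult(config)
  bzm <- tissue_mask(domain, "border_zone")
  n <- length(op$nodes)
  mult <- matrix(0, 12, n)
  is_bz <- bzm[op$nodes]
  mult[, !is_bz] <- mv$normal
  mult[, is_bz] <- mv$border_zone
  if (!is.null(fields)) {
    f <- fields$iks_scale_field[op$nodes]
    f[is.na(f)] <- 1
    mult[4, ] <- mult[4, ] * f
  }
  mult
}

# per-node initial state matrix: class-level resting states (the resting
# voltage is essentially I_Ks-independent)
tissue_resting_states <- function(domain, config, op) {
  mv <- config_mult(config)
  rest <- lapply(mv, function(m) {
    st <- cpp_cell_default_state()
    for (k in 1:30) {
      v0 <- st[1]
      st <- cpp_cell_steps(st, m, 0, config$dt_reaction,
                           round(100 / config$dt_reaction), 0L)$state
      if (abs(st[1] - v0) < 1e-2) break
    }
    st
  })
  bzm <- tissue_mask(domain, "border_zone")
  n <- length(op$nodes)
  S <- matrix(0, 19, n)
  is_bz <- bzm[op$nodes]
  S[, !is_bz] <- rest$normal
  S[, is_bz] <- rest$border_zone
  S
}

#' Run a monodomain simulation
#'
#' @param domain A `tissue_domain`.
#' @param fields A `coordinate_fields` object (or `NULL` for a baseline
#'   run with no I_Ks scaling).
#' @param config A [sim_config()].
#' @param stimuli List of [stimulus()] objects (times within
#'   `[t0, t0 + duration]`).
#' @param initial_state Optional full tissue state from a previous movie
#'   (`movie$final_state`) for protocol chaining.
#' @param t0 Start time (ms); stimulus onsets are absolute.
#' @param record_stride Override of `config$record_stride` (ms).
#' @param duration Override of `config$duration` (ms).
#' @return Object of class `voltage_movie`: equally spaced voltage
#'   `frames` (compact node x frame) with `frame_t`, dense `probe_t` /
#'   `probe_vm` traces, `final_state` for chaining, and the compact node
#'   mapping. Scar/outside nodes are absent from the compact state and
#'   render as `NA` in [movie_frame()].
#' @export
run_simulation <- function(domain, fields, config, stimuli,
                           initial_state = NULL, t0 = 0,
                           record_stride = NULL, duration = NULL) {
  op <- build_diffusion_operator(domain, config)
  run_simulation_op(domain, fields, config, stimuli, op,
                    initial_state = initial_state, t0 = t0,
                    record_stride = record_stride, duration = duration)
}

# internal variant reusing a prebuilt operator (protocol loops)
run_simulation_op <- function(domain, fields, config, stimuli, op,
                              initial_state = NULL, t0 = 0,
                              record_stride = NULL, duration = NULL) {
  duration <- duration %||% config$duration
  record_stride <- record_stride %||% config$record_stride
  n <- length(op$nodes)
  S <- initial_state %||% tissue_resting_states(domain, config, op)
  stopifnot(ncol(S) == n)
  idx <- matrix(NA_integer_, op$shape[1], op$shape[2])
  idx[op$nodes] <- seq_len(n)

  n_stim <- length(stimuli)
  s_on <- numeric(n_stim); s_dur <- numeric(n_stim); s_amp <- numeric(n_stim)
  s_idx <- integer(0); s_ptr <- integer(n_stim + 1)
  for (q in seq_len(n_stim)) {
    st <- stimuli[[q]]
    if (st$t_on < t0 || st$t_on > t0 + duration)
      stop("stimulus onset outside the simulated window")
    nodes_q <- stim_nodes(domain, st)
    s_on[q] <- st$t_on; s_dur[q] <- st$duration; s_amp[q] <- st$amplitude
    s_idx <- c(s_idx, idx[nodes_q] - 1L)
    s_ptr[q + 1] <- length(s_idx)
  }

  probes <- config$snapshot_nodes
  probe_idx <- if (!is.null(probes)) {
    pm <- matrix(as.integer(probes), ncol = 2)
    pi <- idx[pm]
    if (anyNA(pi)) stop("configuration error: probe on a non-conducting node")
    pi
  } else integer(0)

  mult <- node_mult_matrix(domain, fields, config, op)
  sub <- round(config$dt_diffusion / config$dt_reaction)
  out <- cpp_run_monodomain(S, mult, op$p, op$j, op$x, config$dt_reaction,
                            as.integer(sub), duration, t0, s_on, s_dur,
                            s_amp, s_idx, s_ptr,
                            record_stride %||% 0,
                            as.integer(probe_idx - 1L))
  structure(list(frames = out$frames, frame_t = out$frame_t,
                 probe_t = out$probe_t, probe_vm = out$probe_vm,
                 probe_sites = probes, final_state = out$state,
                 nodes = op$nodes, shape = op$shape, dx = domain$dx,
                 t0 = t0, t1 = t0 + duration,
                 record_stride = record_stride,
                 variant = if (!is.null(fields)) fields$variant else "baseline"),
            class = "voltage_movie")
}

#' @export
print.voltage_movie <- function(x, ...) {
  cat(sprintf(
    "<voltage_movie> t = [%g, %g] ms | %d frames (stride %g ms), %d probes, %d conducting nodes on %d x %d grid\n",
    x$t0, x$t1, length(x$frame_t), x$record_stride %||% 0,
    if (is.null(x$probe_sites)) 0L else nrow(x$probe_sites),
    length(x$nodes), x$shape[1], x$shape[2]))
  invisible(x)
}

#' Extract one voltage frame as a full grid
#' @param movie A `voltage_movie`.
#' @param k Frame index.
#' @return Matrix of voltages; `NA` at scar/outside nodes.
#' @export
movie_frame <- function(movie, k) {
  v <- matrix(NA_real_, movie$shape[1], movie$shape[2])
  v[movie$nodes] <- movie$frames[, k]
  v
}

#' Probe voltage trace
#' @param movie A `voltage_movie`.
#' @param probe Probe index (row of `probe_sites`).
#' @return Data frame `t`, `vm`.
#' @export
probe_trace <- function(movie, probe = 1) {
  data.frame(t = movie$probe_t, vm = movie$probe_vm[, probe])
}

#' Find the diastolic capture threshold at a site
#'
#' Doubling search on the stimulus amplitude: the weakest power-of-two
#' multiple of `start_amp` whose single pulse from rest elicits a
#' propagated response (capture at a sentinel probe >= 5 mm away).
#'
#' @param domain,fields,config See [run_simulation()].
#' @param site 1-based `(row, col)` pacing node.
#' @param start_amp Starting (weakest) amplitude, uA/uF.
#' @param max_doublings Search cap.
#' @return Amplitude (uA/uF, negative).
#' @export
find_diastolic_threshold <- function(domain, fields, config, site,
                                     start_amp = -8, max_doublings = 8) {
  sent <- pick_sentinel(domain, site, 5)
  cfg <- config
  cfg$snapshot_nodes <- rbind(site, sent)
  op <- build_diffusion_operator(domain, cfg)
  amp <- start_amp
  for (k in seq_len(max_doublings)) {
    mv <- run_simulation_op(domain, fields, cfg,
                            list(stimulus(site, t_on = 5,
                                          duration = cfg$stim_duration,
                                          amplitude = amp,
                                          radius = cfg$stim_radius)),
                            op, record_stride = 0, duration = 80)
    if (detect_capture(mv, site_probe = 1, sentinel_probe = 2,
                       stim_time = 5,
                       dist_mm = site_distance(site, sent, domain$dx)))
      return(amp)
    amp <- amp * 2
  }
  stop("protocol error: no capture up to amplitude ", amp / 2)
}

site_distance <- function(a, b, dx) sqrt(sum((a - b)^2)) * dx

# nearest conducting node at least min_mm from the site (prefer ~1.5x)
pick_sentinel <- function(domain, site, min_mm = 5) {
  cond <- tissue_mask(domain, "conducting")
  cand <- which(cond, arr.ind = TRUE)
  d <- sqrt((cand[, 1] - site[1])^2 + (cand[, 2] - site[2])^2) * domain$dx
  ok <- d >= min_mm
  if (!any(ok)) stop("configuration error: no conducting node >= min_mm away")
  cand <- cand[ok, , drop = FALSE]
  cand[which.min(abs(d[ok] - 1.5 * min_mm)), ]
}
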