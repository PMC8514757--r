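# Programmed electrical stimulation: S1 drive trains, earliest-timed (ETS)
# and exact-timed (XTS) premature stimuli S2-S4, capture detection, and
# VT-induction bookkeeping.

#' S1 drive-train onset times
#'
#' @param bcl Basic cycle length (ms).
#' @param s1_count Number of S1 stimuli.
#' @return Arithmetic sequence `0, bcl, ..., (s1_count - 1) * bcl`.
#' @export
s1_train_times <- function(bcl, s1_count = 6) {
  stopifnot(bcl > 0, s1_count >= 1)
  (seq_len(s1_count) - 1) * bcl
}

#' Pacing protocol record
#'
#' @param site_index Which pacing site (1-based index into the domain's
#'   pacing sites).
#' @param bcl S1 basic cycle length (ms), 600 or 350 in the standard grid.
#' @param s1_count Number of S1 stimuli (default 6).
#' @param coupling_intervals S2(-S4) coupling intervals (ms); discovered by
#'   the ETS search, required up front for XTS.
#' @param mode `"ETS"` (earliest timed stimulus: couplings found at the
#'   minimal capturing interval) or `"XTS"` (exact timed stimulus:
#'   couplings replayed from a baseline induction).
#' @param search_resolution ETS coupling search step (ms).
#' @return Object of class `pacing_protocol`.
#' @export
pacing_protocol <- function(site_index = 1, bcl = 600, s1_count = 6,
                            coupling_intervals = numeric(0),
                            mode = c("ETS", "XTS"), search_resolution = 5) {
  mode <- match.arg(mode)
  stopifnot(all(coupling_intervals > 0), length(coupling_intervals) <= 3)
  if (mode == "XTS" && !length(coupling_intervals))
    stop("XTS requires explicit coupling intervals from a baseline induction")
  structure(list(site_index = site_index, bcl = bcl, s1_count = s1_count,
                 coupling_intervals = coupling_intervals, mode = mode,
                 search_resolution = search_resolution),
            class = "pacing_protocol")
}

#' @export
print.pacing_protocol <- function(x, ...) {
  cat(sprintf("<pacing_protocol> %s | site %d, BCL %g ms x %d S1, couplings: %s\n",
              x$mode, x$site_index, x$bcl, x$s1_count,
              if (length(x$coupling_intervals))
                paste(x$coupling_intervals, collapse = ", ") else "(none)"))
  invisible(x)
}

probe_upstrokes <- function(movie, probe, threshold = -40) {
  v <- movie$probe_vm[, probe]
  t <- movie$probe_t
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  if (!length(up)) return(numeric(0))
  # linear interpolation within the step
  t[up] + (t[up + 1] - t[up]) * (threshold - v[up]) / (v[up + 1] - v[up])
}

#' Capture detection for one stimulus
#'
#' Capture requires a pacing-site upstroke (-40 mV upward crossing) within
#' 15 ms of the stimulus onset and a sentinel upstroke in the
#' distance-consistent window (a propagated, not local-only, response).
#' In the single-node (single-cell) limit there is no sentinel and the
#' site criterion alone decides.
#'
#' @param movie A `voltage_movie` with dense probe traces.
#' @param site_probe,sentinel_probe Probe indices (columns of
#'   `movie$probe_vm`); `sentinel_probe = NA` for the single-cell limit.
#' @param stim_time Stimulus onset (ms).
#' @param dist_mm Site-sentinel distance (mm).
#' @param cv_min Slowest admissible propagation speed (mm/ms) used for the
#'   sentinel window.
#' @return Logical.
#' @export
detect_capture <- function(movie, site_probe, sentinel_probe, stim_time,
                           dist_mm = 0, cv_min = 0.1) {
  if (is.null(movie$probe_vm) || !ncol(movie$probe_vm))
    stop("configuration error: capture detection requires probe traces")
  ups <- probe_upstrokes(movie, site_probe)
  site_ok <- any(ups > stim_time & ups <= stim_time + 15)
  if (!site_ok) return(FALSE)
  if (is.na(sentinel_probe)) return(TRUE)
  sup <- probe_upstrokes(movie, sentinel_probe)
  any(sup > stim_time & sup <= stim_time + 15 + dist_mm / cv_min)
}

# shared machinery -----------------------------------------------------

protocol_setup <- function(domain, fields, config, site_index) {
  if (is.null(domain$pacing_sites) || nrow(domain$pacing_sites) < site_index)
    stop("configuration error: domain lacks pacing site ", site_index)
  site <- domain$pacing_sites[site_index, ]
  single <- sum(tissue_mask(domain, "conducting")) == 1
  sent <- if (single) NULL else pick_sentinel(domain, site, 5)
  cfg <- config
  cfg$snapshot_nodes <- if (single) rbind(site) else rbind(site, sent)
  if (is.null(cfg$stim_amp))
    cfg$stim_amp <- 2 * find_diastolic_threshold(domain, fields, cfg, site)
  op <- build_diffusion_operator(domain, cfg)
  list(site = site, sentinel = sent, single = single, cfg = cfg, op = op,
       dist_mm = if (single) 0 else site_distance(site, sent, domain$dx))
}

stim_at <- function(setup, t_on) {
  stimulus(setup$site, t_on = t_on, duration = setup$cfg$stim_duration,
           amplitude = setup$cfg$stim_amp, radius = setup$cfg$stim_radius)
}

# incremental upward coupling search from a checkpoint.
# base$state is the tissue state at base$t (no premature stimulus yet);
# couplings are measured from t_prev (the previous stimulus onset).
# Returns the minimal capturing coupling, the pre-stimulus checkpoint at
# that coupling, and the capture movie.
search_coupling <- function(domain, fields, setup, base, t_prev, lb, ub,
                            step, trial_ms) {
  lb <- max(lb, ceiling((base$t - t_prev) / step) * step)
  couplings <- seq(lb, ub, by = step)
  for (cpl in couplings) {
    t_stim <- t_prev + cpl
    if (t_stim > base$t) {   # advance the checkpoint stimulus-free
      adv <- run_simulation_op(domain, fields, setup$cfg, list(), setup$op,
                               initial_state = base$state, t0 = base$t,
                               record_stride = 0,
                               duration = t_stim - base$t)
      base <- list(state = adv$final_state, t = t_stim)
    }
    mv <- run_simulation_op(domain, fields, setup$cfg,
                            list(stim_at(setup, t_stim)), setup$op,
                            initial_state = base$state, t0 = base$t,
                            record_stride = 0, duration = trial_ms)
    if (detect_capture(mv, 1, if (setup$single) NA else 2, t_stim,
                       setup$dist_mm))
      return(list(coupling = cpl, base = base, movie = mv,
                  captured = TRUE))
  }
  list(coupling = NA_real_, base = base, movie = NULL, captured = FALSE)
}

#' Local effective-refractory-interval probe
#'
#' Delivers an S1 drive train at a site and finds, by bounded incremental
#' search, the minimal S1-S2 coupling interval at which an S2 elicits a
#' propagated response.
#'
#' @param domain,fields,config See [run_simulation()].
#' @param site 1-based `(row, col)` pacing node, or a site index into the
#'   domain's pacing sites.
#' @param bcl,s1_count S1 drive train.
#' @param resolution Search step (ms).
#' @param lb Search lower bound (ms).
#' @return Minimal capturing coupling interval (ms).
#' @export
local_erp_probe <- function(domain, fields, config, site = 1, bcl = 600,
                            s1_count = 6, resolution = 5, lb = 50) {
  if (length(site) == 1) {
    setup <- protocol_setup(domain, fields, config, site)
  } else {
    dom <- domain
    dom$pacing_sites <- rbind(as.integer(site))
    setup <- protocol_setup(dom, fields, config, 1)
    domain <- dom
  }
  t_last <- (s1_count - 1) * bcl
  train <- lapply(s1_train_times(bcl, s1_count), function(t0)
    stim_at(setup, t0))
  train_ms <- t_last + setup$cfg$stim_duration + 10
  mv <- run_simulation_op(domain, fields, setup$cfg, train, setup$op,
                          record_stride = 0, duration = train_ms)
  trial_ms <- trial_window_ms(setup)
  res <- search_coupling(domain, fields, setup,
                         base = list(state = mv$final_state, t = train_ms),
                         t_prev = t_last, lb = lb, ub = bcl,
                         step = resolution, trial_ms = trial_ms)
  if (!res$captured)
    stop("protocol error: no capture at any coupling up to the BCL")
  res$coupling
}

trial_window_ms <- function(setup) {
  w <- 40 + 15 + setup$dist_mm / 0.1
  ceiling(w / 10) * 10
}

#' Run the earliest-timed-stimulus (ETS) induction protocol
#'
#' After an S1 drive train, the premature stimulus S2 is delivered at the
#' earliest capturing coupling, found by incremental upward search from
#' (refractory estimate - 50 ms) in steps of `search_resolution`, each
#' trial restarting from the saved pre-stimulus state. If no reentrant
#' arrhythmia follows, S3 and then S4 are escalated the same way on top of
#' the captured predecessors. Induced VT requires at least two reentrant
#' cycles within the observation window.
#'
#' @param domain,fields,config See [run_simulation()].
#' @param site_index Pacing site index.
#' @param bcl S1 basic cycle length (ms).
#' @param s1_count Number of S1 stimuli.
#' @param search_resolution Coupling search step (ms).
#' @param max_premature Maximum number of premature stimuli (3 = up to S4).
#' @param vt_check_ms Stimulus-free window used to decide whether reentry
#'   survives before escalating (ms).
#' @param vt_horizon_ms Total post-stimulus window recorded and analyzed
#'   for an induced VT (ms).
#' @param record_stride Frame stride of the returned movie (ms).
#' @return Object of class `induction_outcome`: the executed
#'   [pacing_protocol()] with discovered couplings, per-stimulus capture
#'   flags, `vt_induced`, `n_cycles`, `cycle_length`,
#'   `post_stimulus_activity_ms`, and `movie` (frames covering the
#'   post-stimulus window).
#' @export
run_ets <- function(domain, fields, config, site_index = 1, bcl = 600,
                    s1_count = 6, search_resolution = 5, max_premature = 3,
                    vt_check_ms = 2000, vt_horizon_ms = 4000,
                    record_stride = 2) {
  setup <- protocol_setup(domain, fields, config, site_index)
  t_last <- (s1_count - 1) * bcl
  train <- lapply(s1_train_times(bcl, s1_count), function(t0)
    stim_at(setup, t0))
  train_ms <- t_last + setup$cfg$stim_duration + 10
  mv <- run_simulation_op(domain, fields, setup$cfg, train, setup$op,
                          record_stride = 0, duration = train_ms)
  # refractory estimate from the single-cell APD at this cycle length: the
  # tissue ERP tracks the local APD; the search starts 50 ms below it
  erp_est <- single_cell_apd_estimate(domain, fields, setup, bcl)
  trial_ms <- trial_window_ms(setup)

  base <- list(state = mv$final_state, t = train_ms)
  t_prev <- t_last
  couplings <- numeric(0)
  captured <- logical(0)
  # snap the search origin to the resolution grid so every tested coupling
  # (and hence every chunk boundary) falls on the diffusion-step lattice
  lb <- max(50, floor((erp_est - 50) / search_resolution) *
              search_resolution)
  outcome <- NULL
  for (stage in seq_len(max_premature)) {
    res <- search_coupling(domain, fields, setup, base, t_prev, lb, bcl,
                           search_resolution, trial_ms)
    if (!res$captured) {
      outcome <- list(vt = NULL, fail = TRUE)
      break
    }
    couplings <- c(couplings, res$coupling)
    captured <- c(captured, TRUE)
    t_stim <- t_prev + res$coupling
    # stimulus-free observation from the pre-stimulus checkpoint
    chk <- run_simulation_op(domain, fields, setup$cfg,
                             list(stim_at(setup, t_stim)), setup$op,
                             initial_state = res$base$state,
                             t0 = res$base$t, record_stride = record_stride,
                             duration = vt_check_ms)
    det <- detect_reentry(chk, post_stimulus_window =
                            c(t_stim + setup$cfg$stim_duration,
                              t_stim + vt_check_ms))
    if (det$reentry) {
      extra <- vt_horizon_ms - vt_check_ms
      if (extra > 0) {
        ext <- run_simulation_op(domain, fields, setup$cfg, list(),
                                 setup$op, initial_state = chk$final_state,
                                 t0 = chk$t1,
                                 record_stride = record_stride,
                                 duration = extra)
        chk <- merge_movies(chk, ext)
        det <- detect_reentry(chk, post_stimulus_window =
                                c(t_stim + setup$cfg$stim_duration,
                                  chk$t1))
      }
      outcome <- list(vt = det, movie = chk, t_laststim = t_stim)
      break
    }
    # escalate: next premature rides on the captured predecessor
    base <- advance_past_stimulus(domain, fields, setup, res, t_stim)
    t_prev <- t_stim
    lb <- max(50, res$coupling - 100)
    outcome <- list(vt = det, movie = chk, t_laststim = t_stim)
  }
  proto <- pacing_protocol(site_index, bcl, s1_count, couplings, "ETS",
                           search_resolution)
  finish_outcome(proto, captured, outcome, setup)
}

advance_past_stimulus <- function(domain, fields, setup, res, t_stim) {
  mv <- run_simulation_op(domain, fields, setup$cfg,
                          list(stim_at(setup, t_stim)), setup$op,
                          initial_state = res$base$state, t0 = res$base$t,
                          record_stride = 0,
                          duration = setup$cfg$stim_duration + 10)
  list(state = mv$final_state, t = mv$t1)
}

single_cell_apd_estimate <- function(domain, fields, setup, bcl) {
  site <- setup$site
  iks <- if (!is.null(fields)) {
    f <- fields$iks_scale_field[site[1], site[2]]
    if (is.na(f)) 1 else f
  } else 1
  cls <- if (tissue_mask(domain, "border_zone")[site[1], site[2]])
    "border_zone" else "normal"
  p <- cell_params(cls, iks_scale = iks,
                   base_gks_calibration = setup$cfg$base_gks_calibration,
                   remodeling_factors = if (cls == "border_zone")
                     setup$cfg$bz_remodeling)
  ex <- setup$cfg$extra_conductance_mult
  m <- mult_vector(p)
  if (!is.null(ex[[cls]])) {
    slot <- c(g_na = 1, g_cal = 2, g_kr = 3, g_ks = 4)
    for (cn in names(ex[[cls]])) m[slot[[cn]]] <- m[slot[[cn]]] * ex[[cls]][[cn]]
  }
  st <- cpp_cell_default_state()
  st <- cpp_cell_steps(st, m, 0, 0.02, 50000L, 0L)$state
  out <- cpp_pace_cell(st, m, 0.02, bcl, 8L, -52, 1, 0L)
  apd <- out$apd90[is.finite(out$apd90)]
  if (!length(apd)) return(250)
  tail(apd, 1)
}

finish_outcome <- function(proto, captured, outcome, setup) {
  vt <- outcome$vt
  movie <- outcome$movie
  post_ms <- if (!is.null(movie)) {
    acts <- frame_activation_times(movie)
    last_act <- suppressWarnings(max(unlist(acts), na.rm = TRUE))
    if (is.finite(last_act))
      max(0, last_act - (outcome$t_laststim + setup$cfg$stim_duration))
    else 0
  } else 0
  structure(list(protocol = proto, captured = captured,
                 vt_induced = isTRUE(vt$reentry),
                 n_cycles = vt$n_cycles %||% 0L,
                 cycle_length = vt$cycle_length %||% NA_real_,
                 post_stimulus_activity_ms = post_ms,
                 protocol_failure = isTRUE(outcome$fail),
                 movie = movie, t_last_stimulus = outcome$t_laststim,
                 site = setup$site, sentinel = setup$sentinel,
                 stim_amp = setup$cfg$stim_amp),
            class = "induction_outcome")
}

#' @export
print.induction_outcome <- function(x, ...) {
  cat(sprintf(
    "<induction_outcome> %s site %d BCL %g | couplings %s | VT: %s (%d cycles, CL %.0f ms), post-stimulus activity %.0f ms\n",
    x$protocol$mode, x$protocol$site_index, x$protocol$bcl,
    if (length(x$protocol$coupling_intervals))
      paste(round(x$protocol$coupling_intervals), collapse = "/")
    else "(none captured)",
    if (x$vt_induced) "induced" else "not induced", x$n_cycles,
    x$cycle_length %||% NA, x$post_stimulus_activity_ms))
  invisible(x)
}

#' Run the exact-timed-stimulus (XTS) replay protocol
#'
#' Re-applies the exact S2-S4 couplings of a (typically baseline-inducing)
#' protocol to another model of the same substrate. A premature stimulus
#' that fails to capture is still delivered (field stimulus) and flagged.
#'
#' @param domain,fields,config See [run_simulation()].
#' @param protocol_from_baseline A [pacing_protocol()] with explicit
#'   coupling intervals.
#' @param vt_horizon_ms Post-stimulus window recorded and analyzed (ms).
#' @param record_stride Frame stride of the returned movie (ms).
#' @return An `induction_outcome` (mode `"XTS"`).
#' @export
run_xts <- function(domain, fields, config, protocol_from_baseline,
                    vt_horizon_ms = 4000, record_stride = 2) {
  proto <- protocol_from_baseline
  if (!length(proto$coupling_intervals))
    stop("XTS requires coupling intervals from a baseline induction")
  setup <- protocol_setup(domain, fields, config, proto$site_index)
  t_last_s1 <- (proto$s1_count - 1) * proto$bcl
  times <- c(s1_train_times(proto$bcl, proto$s1_count),
             t_last_s1 + cumsum(proto$coupling_intervals))
  t_last <- max(times)
  stims <- lapply(times, function(t0) stim_at(setup, t0))
  # phase 1: up to the final stimulus onset (probes only)
  mv1 <- run_simulation_op(domain, fields, setup$cfg,
                           stims[times < t_last], setup$op,
                           record_stride = 0, duration = t_last)
  # phase 2: final stimulus + post-stimulus window with frames
  mv2 <- run_simulation_op(domain, fields, setup$cfg,
                           stims[times == t_last], setup$op,
                           initial_state = mv1$final_state, t0 = t_last,
                           record_stride = record_stride,
                           duration = vt_horizon_ms)
  movie <- merge_movies(mv1, mv2)
  prem_times <- t_last_s1 + cumsum(proto$coupling_intervals)
  captured <- vapply(prem_times, function(ts)
    detect_capture(movie, 1, if (setup$single) NA else 2, ts,
                   setup$dist_mm), logical(1))
  det <- detect_reentry(mv2, post_stimulus_window =
                          c(t_last + setup$cfg$stim_duration, mv2$t1))
  out_proto <- pacing_protocol(proto$site_index, proto$bcl, proto$s1_count,
                               proto$coupling_intervals, "XTS",
                               proto$search_resolution)
  finish_outcome(out_proto, captured,
                 list(vt = det, movie = mv2, t_laststim = t_last), setup)
}

#' Concatenate two chained voltage movies
#' @param m1,m2 `voltage_movie`s with `m2$t0 == m1$t1`.
#' @return Combined `voltage_movie`.
#' @export
merge_movies <- function(m1, m2) {
  stopifnot(abs(m2$t0 - m1$t1) < 1e-6, all(m1$shape == m2$shape))
  out <- m2
  out$t0 <- m1$t0
  out$frames <- if (length(m1$frame_t)) cbind(m1$frames, m2$frames)
                else m2$frames
  out$frame_t <- c(m1$frame_t, m2$frame_t)
  out$probe_t <- c(m1$probe_t, m2$probe_t)
  out$probe_vm <- rbind(m1$probe_vm, m2$probe_vm)
  out
}
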