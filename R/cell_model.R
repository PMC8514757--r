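# Human ventricular ionic cell model (ten Tusscher-Panfilov 2006,
# epicardial parameter set) with infarct border-zone remodeling and a
# multiplicative I_Ks conductance hook.

#' Default border-zone remodeling factors
#'
#' Fractional maximal-conductance multipliers applied to the border-zone
#' cell: peak sodium 0.38, L-type calcium 0.31, rapid delayed rectifier
#' 0.30, slow delayed rectifier 0.20. These reduced depolarizing and
#' repolarizing currents slow conduction and prolong APD in the infarct
#' border zone.
#'
#' @return Named numeric vector of conductance multipliers.
#' @export
bz_remodeling_defaults <- function() {
  c(g_na = 0.38, g_cal = 0.31, g_kr = 0.30, g_ks = 0.20)
}

#' Cell model parameters
#'
#' @param tissue_class `"normal"` or `"border_zone"`.
#' @param iks_scale Dimensionless multiplier (>= 0) on the I_Ks maximal
#'   conductance. The gradient builder produces values in `[1, 2.25]`;
#'   arbitrary positive values are allowed for calibration sweeps.
#' @param base_gks_calibration Multiplier applied to the published baseline
#'   I_Ks conductance, used to pin the APD90 calibration anchor (see
#'   [calibrate_base_gks()]).
#' @param remodeling_factors Named numeric vector of conductance
#'   multipliers in `[0, 1]` (names among `g_na`, `g_cal`, `g_kr`, `g_ks`).
#'   Defaults to [bz_remodeling_defaults()] for border-zone cells and all
#'   ones for normal cells; a normal cell must have all factors equal 1.
#'
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(tissue_class = c("normal", "border_zone"),
                        iks_scale = 1.0, base_gks_calibration = 1.0,
                        remodeling_factors = NULL) {
  tissue_class <- match.arg(tissue_class)
  stopifnot(is.numeric(iks_scale), length(iks_scale) == 1, iks_scale >= 0,
            is.numeric(base_gks_calibration), base_gks_calibration > 0)
  if (is.null(remodeling_factors)) {
    remodeling_factors <- if (tissue_class == "border_zone")
      bz_remodeling_defaults()
    else
      c(g_na = 1, g_cal = 1, g_kr = 1, g_ks = 1)
  }
  rf <- c(g_na = 1, g_cal = 1, g_kr = 1, g_ks = 1)
  rf[names(remodeling_factors)] <- remodeling_factors
  if (any(rf < 0 | rf > 1)) stop("remodeling factors must lie in [0, 1]")
  if (tissue_class == "normal" && any(rf != 1))
    stop("a normal cell must have all remodeling factors equal to 1")
  structure(list(tissue_class = tissue_class, iks_scale = iks_scale,
                 base_gks_calibration = base_gks_calibration,
                 remodeling_factors = rf),
            class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params> ", x$tissue_class,
      sprintf(" | iks_scale=%.4g, base_gks_calibration=%.4g\n",
              x$iks_scale, x$base_gks_calibration))
  if (x$tissue_class == "border_zone")
    cat("  remodeling:", paste(names(x$remodeling_factors),
                               x$remodeling_factors, sep = "=",
                               collapse = ", "), "\n")
  invisible(x)
}

# 12-element multiplier vector consumed by the C++ kernel, in the order
# gNa, gCaL, gKr, gKs, gto, gK1, gpCa, gpK, gbNa, gbCa, pNaK, kNaCa
mult_vector <- function(params) {
  rf <- params$remodeling_factors
  c(rf[["g_na"]], rf[["g_cal"]], rf[["g_kr"]],
    rf[["g_ks"]] * params$iks_scale * params$base_gks_calibration,
    1, 1, 1, 1, 1, 1, 1, 1)
}

state_names <- function() {
  c("vm", "m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d",
    "f", "f2", "fcass", "rbar", "cai", "casr", "cass", "nai", "ki")
}

#' Published initial state of the cell model
#'
#' @return Named numeric vector of the 19 state variables (membrane voltage
#'   in mV, 13 gating variables in `[0,1]`, 5 concentrations in mM).
#' @export
cell_default_state <- function() {
  setNames(cpp_cell_default_state(), state_names())
}

#' Resting state of a parameterized cell
#'
#' Integrates the cell without stimulus until the membrane voltage drifts
#' by less than `tol` mV over 100 ms, starting from the published initial
#' conditions.
#'
#' @param params A [cell_params()] object.
#' @param dt Integration step (ms).
#' @param max_ms Maximum settling time (ms).
#' @param tol Voltage drift tolerance (mV per 100 ms).
#' @return Named state vector at rest.
#' @export
cell_resting_state <- function(params = cell_params(), dt = 0.02,
                               max_ms = 5000, tol = 1e-2) {
  st <- cell_default_state()
  mv <- mult_vector(params)
  elapsed <- 0
  repeat {
    v0 <- st[["vm"]]
    st <- setNames(cpp_cell_steps(st, mv, 0, dt, round(100 / dt), 0L)$state,
                   state_names())
    elapsed <- elapsed + 100
    if (abs(st[["vm"]] - v0) < tol || elapsed >= max_ms) break
  }
  st
}

#' Advance a single cell
#'
#' Rush-Larsen update for the gating variables (clamped to `[0,1]`),
#' forward Euler for voltage and concentrations.
#'
#' @param state Named 19-element state vector (see [cell_default_state()]).
#' @param params A [cell_params()] object.
#' @param i_stim Stimulus current (uA/uF); cathodal stimuli are negative.
#' @param dt Time step (ms); must be positive and at most 0.05.
#' @param n_steps Number of steps to take.
#' @param record_stride Record the voltage every `record_stride` steps
#'   (0 = no trace).
#' @return List with the advanced `state` and, if requested, `t`/`vm`
#'   trace vectors.
#' @export
step_cell <- function(state, params = cell_params(), i_stim = 0, dt = 0.02,
                      n_steps = 1L, record_stride = 0L) {
  stopifnot(dt > 0, dt <= 0.05, n_steps >= 1)
  out <- cpp_cell_steps(as.numeric(state), mult_vector(params), i_stim, dt,
                        as.integer(n_steps), as.integer(record_stride))
  out$state <- setNames(out$state, state_names())
  out
}

#' Measure steady-state APD90 of a paced cell
#'
#' Paces a single cell from rest to quasi-steady state and measures the
#' action potential duration at 90% repolarization of the final beat:
#' the interval from the -40 mV upward threshold crossing to
#' repolarization to 90% of that beat's amplitude (peak minus resting
#' voltage).
#'
#' @param params A [cell_params()] object.
#' @param pacing_cl Pacing cycle length (ms); must exceed the expected APD.
#' @param n_beats Number of beats (>= 20 for steady state).
#' @param dt Integration step (ms).
#' @param stim_amp,stim_dur Stimulus amplitude (uA/uF) and duration (ms).
#' @return Object of class `apd_measurement`: `apd90`, `resting_vm`,
#'   `peak_vm` (mV), `cycle_index`, `pacing_cl`, and `steady` (FALSE with a
#'   warning when the final beats alternate by more than 2 ms).
#' @export
measure_apd90 <- function(params = cell_params(), pacing_cl = 600,
                          n_beats = 50, dt = 0.02, stim_amp = -52,
                          stim_dur = 1) {
  stopifnot(n_beats >= 20, pacing_cl > 0)
  st <- cell_resting_state(params, dt = dt)
  out <- cpp_pace_cell(st, mult_vector(params), dt, pacing_cl,
                       as.integer(n_beats), stim_amp, stim_dur, 0L)
  apd <- out$apd90
  last <- n_beats
  if (!is.finite(apd[last]))
    stop("no-capture: no action potential elicited on the final beat")
  if (apd[last] >= pacing_cl)
    stop("pacing_cl must exceed the measured APD")
  steady <- abs(apd[last] - apd[last - 1]) <= 2
  if (!steady)
    warning(sprintf(
      "non-steady-state: final beats differ by %.1f ms (alternans?)",
      abs(apd[last] - apd[last - 1])))
  structure(list(apd90 = apd[last], resting_vm = out$rest[last],
                 peak_vm = out$peak[last], cycle_index = last,
                 pacing_cl = pacing_cl, steady = steady,
                 apd_train = apd),
            class = "apd_measurement")
}

#' @export
print.apd_measurement <- function(x, ...) {
  cat(sprintf(
    "<apd_measurement> APD90 = %.1f ms (beat %d @ CL %g ms), rest %.1f mV, peak %.1f mV\n",
    x$apd90, x$cycle_index, x$pacing_cl, x$resting_vm, x$peak_vm))
  invisible(x)
}

#' Calibrate the baseline I_Ks conductance to an APD90 anchor
#'
#' Finds the multiplier on the published baseline I_Ks conductance such
#' that a normal cell with `iks_scale = 1` paced at `pacing_cl` has an
#' APD90 within `tol` of `target_apd90`. APD90 is monotone decreasing in
#' the multiplier, so bisection is used.
#'
#' @param target_apd90 Target APD90 (ms).
#' @param pacing_cl Pacing cycle length (ms).
#' @param tol Tolerance on the achieved APD90 (ms).
#' @param bounds Multiplier search bracket.
#' @param n_beats,dt Passed to [measure_apd90()].
#' @return The calibrated multiplier (use as `base_gks_calibration`).
#' @export
calibrate_base_gks <- function(target_apd90, pacing_cl = 600, tol = 1,
                               bounds = c(0.1, 10), n_beats = 50,
                               dt = 0.02) {
  f <- function(mult) {
    p <- cell_params("normal", iks_scale = 1, base_gks_calibration = mult)
    suppressWarnings(
      measure_apd90(p, pacing_cl = pacing_cl, n_beats = n_beats,
                    dt = dt)$apd90)
  }
  lo <- bounds[1]; hi <- bounds[2]
  f_lo <- f(lo); f_hi <- f(hi)   # f_lo is the longest achievable APD
  if (target_apd90 > f_lo + tol || target_apd90 < f_hi - tol)
    stop(sprintf(
      "calibration failure: target %.1f ms outside achievable bracket [%.1f, %.1f] ms",
      target_apd90, f_hi, f_lo))
  for (it in 1:60) {
    mid <- sqrt(lo * hi)   # bisect in log space: conductance is a ratio
    fm <- f(mid)
    if (abs(fm - target_apd90) <= tol) return(mid)
    if (fm > target_apd90) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-6) break
  }
  mid
}

#' Sweep APD90 over I_Ks scaling factors
#'
#' @param iks_scales Numeric vector of I_Ks scaling factors.
#' @param base_gks_calibration Calibration multiplier (see
#'   [calibrate_base_gks()]).
#' @param pacing_cl,n_beats,dt Passed to [measure_apd90()].
#' @param file Optional path; when given, the sweep is written as
#'   tab-delimited text with columns `iks_scale`, `pacing_cl`, `apd90_ms`.
#' @return Data frame with columns `iks_scale`, `pacing_cl`, `apd90_ms`.
#' @export
apd_sweep <- function(iks_scales = c(1, 1.25, 1.5, 1.75, 2, 2.25),
                      base_gks_calibration = 1, pacing_cl = 600,
                      n_beats = 50, dt = 0.02, file = NULL) {
  apd <- vapply(iks_scales, function(s) {
    p <- cell_params("normal", iks_scale = s,
                     base_gks_calibration = base_gks_calibration)
    suppressWarnings(
      measure_apd90(p, pacing_cl = pacing_cl, n_beats = n_beats, dt = dt)$apd90)
  }, numeric(1))
  out <- data.frame(iks_scale = iks_scales, pacing_cl = pacing_cl,
                    apd90_ms = apd)
  if (!is.null(file))
    write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  out
}

#' Serialize cell parameters to a JSON config block
#' @param params A [cell_params()] object.
#' @return JSON string (a `cell:` config block).
#' @export
cell_params_to_json <- function(params) {
  x <- unclass(params)
  x$remodeling_factors <- as.list(x$remodeling_factors)  # keep names
  jsonlite::toJSON(list(cell = x), auto_unbox = TRUE, digits = NA)
}

#' Restore cell parameters from a JSON config block
#' @param json JSON string produced by [cell_params_to_json()].
#' @return A [cell_params()] object.
#' @export
cell_params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)$cell
  cell_params(x$tissue_class, x$iks_scale, x$base_gks_calibration,
              unlist(x$remodeling_factors))
}
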