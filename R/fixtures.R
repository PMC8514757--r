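# Reduced desk-scale test substrates with known geometry, used by the
# test-suite and the example analyses: a homogeneous sheet, a scar annulus
# for anatomical reentry, and a two-blob scar with a border-zone channel
# ("fig8") that supports figure-of-eight reentry under programmed
# stimulation. The matching simulation configuration shortens the action
# potential (stronger I_Ks) and slows conduction so that reentrant
# wavelengths fit a centimeter-scale sheet.

#' Homogeneous conducting sheet
#'
#' @param nr,nc Grid size (nodes).
#' @param dx Node spacing (mm).
#' @param pacing_sites Optional pacing sites; default three sites on the
#'   apical band.
#' @return A `tissue_domain` of all-normal tissue.
#' @export
fixture_sheet <- function(nr = 96, nc = 96, dx = 0.25, pacing_sites = NULL) {
  tc <- matrix(0L, nr, nc)
  if (is.null(pacing_sites))
    pacing_sites <- cbind(rep(max(nr - 3, 1), 3),
                          pmax(1, pmin(nc, round(nc * c(0.2, 0.5, 0.8)))))
  tissue_domain(tc, dx = dx, pacing_sites = pacing_sites)
}

#' Scar-annulus fixture (anatomical reentry in a ring corridor)
#'
#' A conducting ring between two scar regions (a central disc and the
#' outer field). With a phase-ramp initial state ([crossfield_state()] +
#' [annulus_age_ramp()]) a wave circulates the ring at a cycle length of
#' about (mid-ring perimeter / conduction velocity), which gives the
#' analytic circulation-time oracle used in the tests.
#'
#' @param nr,nc,dx Grid geometry.
#' @param r_in,r_out Inner/outer conducting-ring radii (mm).
#' @return A `tissue_domain`.
#' @export
fixture_annulus <- function(nr = 96, nc = 96, dx = 0.25, r_in = 8,
                            r_out = 11) {
  tc <- matrix(2L, nr, nc)
  cen <- c((nr + 1) / 2, (nc + 1) / 2)
  d2 <- ((row(tc) - cen[1])^2 + (col(tc) - cen[2])^2) * dx^2
  tc[d2 > r_in^2 & d2 <= r_out^2] <- 0L
  ring <- which(tc == 0L, arr.ind = TRUE)
  pick <- ring[c(1, floor(nrow(ring) / 3), floor(2 * nrow(ring) / 3)), ,
               drop = FALSE]
  tissue_domain(tc, dx = dx, pacing_sites = pick)
}

#' Figure-of-eight fixture: two scar blobs with a border-zone channel
#'
#' Two rectangular scar regions separated by a conducting channel of
#' border-zone tissue. The border-zone cells have a longer APD than the
#' surrounding (I_Ks-boosted) normal tissue, so a sufficiently premature
#' stimulus from the apical side blocks in the channel, conducts around
#' both scar blobs, and re-enters the recovered channel retrogradely --
#' the classic figure-of-eight double-loop circuit.
#'
#' @param nr,nc,dx Grid geometry.
#' @param channel_halfwidth_nodes Channel half-width (nodes).
#' @param with_channel `FALSE` fuses the scar into one bar (no channel).
#' @return A `tissue_domain`; pacing sites sit on the apical band below
#'   the channel mouth.
#' @export
fixture_fig8 <- function(nr = 96, nc = 96, dx = 0.25,
                         channel_halfwidth_nodes = 4,
                         with_channel = TRUE) {
  tc <- matrix(0L, nr, nc)
  mid <- round(nc / 2)
  hw <- channel_halfwidth_nodes
  r0 <- round(nr * 0.22); r1 <- round(nr * 0.70)
  c0 <- round(nc * 0.10); c1 <- round(nc * 0.90)
  tc[r0:r1, c0:c1] <- 2L
  if (with_channel) {
    ch_cols <- (mid - hw):(mid + hw)
    tc[r0:r1, ch_cols] <- 1L  # channel fill: border-zone tissue
    # border-zone rim one node thick around the scar blobs
    scar <- tc == 2L
    rim <- cpp_dilate_disc(scar, 1.5) & !scar & tc != 1L
    tc[rim] <- 1L
  }
  tissue_domain(tc, dx = dx,
                pacing_sites = cbind(rep(min(nr - 3, nr), 3),
                                     pmax(1, pmin(nc, round(nc * c(0.2, 0.5, 0.8))))))
}

#' Simulation configuration for the desk-scale fixtures
#'
#' Conduction slowed (longitudinal CV about 23 cm/s) and normal-tissue
#' APD shortened by a strong I_Ks boost so that the reentrant wavelength
#' fits a 3.2 cm sheet; border-zone cells keep their remodeled (long-APD,
#' slow) phenotype, giving the channel a longer refractory period than
#' the bulk.
#'
#' @param duration Simulated time (ms).
#' @param record_stride Frame stride (ms).
#' @param normal_gks_boost Extra I_Ks multiplier on normal tissue.
#' @param bz_gks_boost Extra I_Ks multiplier on border-zone tissue.
#' @param D_l Longitudinal diffusion (cm^2/ms).
#' @param ... Passed on to [sim_config()].
#' @return A [sim_config()].
#' @export
fixture_sim_config <- function(duration = 1000, record_stride = 2,
                               normal_gks_boost = 6, bz_gks_boost = 6,
                               gcal_factor = 0.5, D_l = 2.5e-4, ...) {
  sim_config(duration = duration, record_stride = record_stride,
             D_l = D_l, D_t = D_l,  # isotropic: the reduced sheets are
                                    # fiber-free so arcs conduct uniformly
             extra_conductance_mult = list(
               normal = c(g_ks = normal_gks_boost, g_cal = gcal_factor),
               border_zone = c(g_ks = bz_gks_boost, g_cal = gcal_factor)),
             ...)
}

# full single-cell state `t_after` ms after a threshold upstroke
cell_state_at_phase <- function(mult, t_after, dt = 0.02) {
  st <- cpp_cell_default_state()
  st <- cpp_cell_steps(st, mult, 0, dt, 50000L, 0L)$state  # settle 1 s
  st <- cpp_cell_steps(st, mult, -52, dt, round(1 / dt), 0L)$state
  if (t_after > 1)
    st <- cpp_cell_steps(st, mult, 0, dt, round((t_after - 1) / dt), 0L)$state
  st
}

#' Cross-field initial state for direct reentry initialization
#'
#' Builds a full tissue state carrying the history of a virtual wave: each
#' node with a finite `age` starts as a single cell `age` ms after its
#' upstroke (0 = just excited, larger = further into
#' repolarization/recovery), all other nodes at rest. A linear age ramp
#' behind an excited flank reproduces a traveling wave's refractory tail,
#' so the front can only move away from the ramp - which starts a
#' circulating wavefront without any pacing protocol.
#'
#' @param domain A `tissue_domain`.
#' @param config A [sim_config()].
#' @param age Numeric grid matrix of upstroke ages (ms); `NA` = resting.
#' @param age_bin Ages are quantized to this resolution (ms) so only a few
#'   single-cell integrations are needed.
#' @return 19 x n state matrix aligned with the compact conducting nodes
#'   (for `run_simulation(initial_state = )`).
#' @export
crossfield_state <- function(domain, config, age, age_bin = 10) {
  op <- build_diffusion_operator(domain, config)
  S <- tissue_resting_states(domain, config, op)
  mv <- config_mult(config)
  bzm <- tissue_mask(domain, "border_zone")[op$nodes]
  a <- pmax(round(age[op$nodes] / age_bin) * age_bin, 2)
  for (cls in c("normal", "border_zone")) {
    sel_cls <- if (cls == "normal") !bzm else bzm
    ages <- unique(a[sel_cls & !is.na(a)])
    for (ag in ages) {
      st <- cell_state_at_phase(mv[[cls]], ag)
      S[, sel_cls & !is.na(a) & a == ag] <- st
    }
  }
  S
}

#' Age ramp around an annulus (virtual circulating-wave history)
#'
#' @param nr,nc Grid size.
#' @param center `(row, col)` center.
#' @param head_deg Angular position of the wavefront head (just excited).
#' @param span_deg Angular extent of the tail behind the head (degrees,
#'   increasing angle = older).
#' @param max_age Age (ms) at the oldest end of the tail; must exceed
#'   the local APD so the tail blends smoothly into resting tissue.
#' @return Age matrix for [crossfield_state()] (`NA` outside the tail).
#' @export
annulus_age_ramp <- function(nr, nc, center, head_deg = 0, span_deg = 220,
                             max_age = 240) {
  ang <- atan2(row(matrix(0, nr, nc)) - center[1],
               col(matrix(0, nr, nc)) - center[2]) * 180 / pi
  rel <- (ang - head_deg) %% 360
  age <- matrix(NA_real_, nr, nc)
  inside <- rel <= span_deg
  age[inside] <- rel[inside] / span_deg * max_age
  age
}

#' Sector masks around a point (for annulus cross-field initialization)
#'
#' @param nr,nc Grid size.
#' @param center `(row, col)` center.
#' @param from_deg,to_deg Angular range (degrees, counterclockwise from
#'   the +column axis).
#' @return Logical matrix.
#' @export
sector_mask <- function(nr, nc, center, from_deg, to_deg) {
  ang <- atan2(row(matrix(0, nr, nc)) - center[1],
               col(matrix(0, nr, nc)) - center[2]) * 180 / pi
  ang <- (ang + 360) %% 360
  from <- (from_deg + 360) %% 360; to <- (to_deg + 360) %% 360
  if (from <= to) ang >= from & ang <= to else ang >= from | ang <= to
}
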