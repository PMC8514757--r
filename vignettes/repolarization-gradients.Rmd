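---
title: "Methods: repolarization gradients and post-infarct VT dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repolarization gradients and post-infarct VT dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package models

After a myocardial infarction, surviving tissue around the scar (the
infarct border zone) conducts slowly and recovers late; narrow conducting
channels through or around the scar can sustain reentrant ventricular
tachycardia (VT). Independently of the scar, the healthy ventricle carries
systematic repolarization gradients: action potential duration (APD)
shortens from base to apex and from endocardium to epicardium, largely
through regional differences in the slow delayed rectifier potassium
current (I_Ks), the current through which beta-adrenergic tone modulates
repolarization. `vtgrad` asks, at desk scale, how such apicobasal (AB) and
transmural (TM) repolarization gradients change three things about
post-infarct VT: whether it is inducible, which reentrant pathway it uses,
and where the wavefront exits the circuit.

The study design is a grid of in-silico programmed-stimulation experiments
over four model variants of the same substrate — `baseline` (no gradient),
`ab_only`, `tm_only`, and `ab_tm` (both axes) — three pacing sites, two S1
cycle lengths (600 and 350 ms), and two premature-stimulus policies (ETS:
couplings re-discovered at the earliest capturing interval; XTS: the exact
couplings that induced the baseline VT replayed verbatim).

# Membrane model and the I_Ks hook

The ionic membrane model is the ten Tusscher–Panfilov (2006) human
ventricular model with the epicardial parameter set; it is integrated with
Rush–Larsen exponential updates for the twelve voltage-dependent gates
(tabulated over [-120, 100] mV at 0.05 mV with linear interpolation, the
decay factors rebuilt whenever the step size changes) and forward Euler
for the voltage and the six concentration/CaSS-coupled states, at a
default reaction step of 0.02 ms. Gates are clamped to [0, 1] after every
step.

Two multiplicative hooks modify the published conductances:

* `base_gks_calibration`, a single multiplier on the published I_Ks
  maximal conductance. The published single-cell settings behind the
  target APD values are not part of this artifact's inputs, so the package
  pins the anchor by calibration: `calibrate_base_gks(303)` bisects (in
  log space) on the multiplier until a normal cell paced at cycle length
  600 ms for 50 beats yields APD90 = 303 ms at gradient scale 1. APD90 is
  monotone decreasing in the multiplier, so the bisection is well posed.
  With that anchor fixed, the scales 1.5 and 2.25 *predict* APD90 near 272
  and 242 ms; the acceptance suite checks both within +/- 10 ms. The
  pacing rate for the calibration (CL 600 ms, 50 beats, single cell) is a
  package choice: it matches the slower S1 drive train of the induction
  protocol.
* `iks_scale`, the per-node gradient multiplier in [1, 2.25] built from
  the coordinate fields (below).

Border-zone cells use fractional conductances on top of the same model:
peak sodium 0.38, L-type calcium 0.31, rapid delayed rectifier 0.30, slow
delayed rectifier 0.20. This yields the two signature border-zone
properties the circuits rely on: slower conduction (reduced sodium
current) and a longer, later-recovering action potential (reduced
repolarizing currents). All factors are exposed in `cell_params()` and the
simulation configuration.

# Substrate geometry

Patient-derived ventricular anatomy is out of scope; the generator
replaces it with a rectangular sheet whose axes carry the anatomical
semantics: rows run base (row 1) to apex, columns endocardium (column 1)
to epicardium. Scar is drawn by thresholding a Gaussian-smoothed random
field modulated by a localization envelope centered at a normalized
apicobasal position (default 0.75 — the anterior/apical localization seen
in the emulated cohort), with the threshold chosen by quantile so the
achieved scar node fraction matches the target by construction. A
conducting channel is carved through the scar and filled with border-zone
tissue, the scar is re-thresholded outside the channel so the carve does
not bite into the scar budget, and the border zone is grown as a
morphological rim to its own target count. Border-zone pockets fully
enclosed by scar are absorbed into the scar (they would be electrically
inert and violate the connectivity invariant). Defaults reproduce the
emulated cohort statistics: scar 12.6% and border zone 6.8% of myocardial
nodes. Generation is deterministic per seed and rejection-resamples (cap
20) if either achieved fraction strays more than 20% relative from its
target. Because the thresholds are quantile-pinned, the across-seed spread
of the achieved fractions is essentially zero; the emulated cohort's
across-patient spread can be reproduced by varying the target fractions
per substrate, which are ordinary parameters.

The default fiber field rotates linearly across the transmural axis
(+/- 60 degrees); pacing sites are three non-scar nodes on the apical band
spaced at least 5 mm apart (the "RV-apex analog"), with a documented
fallback to half the spacing on sheets too small to honor it.

# Coordinate fields

* Apicobasal coordinate: multi-source Dijkstra distance from the base
  edge over conducting tissue, 8-connected with Euclidean step weights, so
  paths detour around scar; normalized by the per-domain maximum (the
  normalization length is not specified externally, so the domain maximum
  is used). The field is checked against an independent shortest-path
  oracle (an explicit igraph graph) exactly, over randomized obstacle
  grids.
* Transmural coordinate: the Laplace equation with Dirichlet values 0/1 on
  the endocardial/epicardial edges and no-flux on the remaining boundaries
  and scar interfaces, discretized with a 5-point stencil that simply
  drops non-conducting neighbors. The sparse system is solved directly
  (Cholesky via the Matrix package) and the relative residual is verified
  below 1e-8; a direct dense solve is the test oracle on holed grids.
* Scaling field: each axis contributes a factor `1 + 0.5 u`, so a single
  axis spans [1, 1.5]; the combined variant multiplies the two factors and
  spans [1, 2.25], reaching 2.25 exactly at the apical epicardial corner.
  The gradient is applied to normal tissue only by default — the
  border-zone cell already carries a remodeled (reduced) I_Ks, and scaling
  on top of remodeling is not well constrained — with `bz_gradient = TRUE`
  available to scale it anyway.

# Tissue model

The monodomain reaction–diffusion equation is solved by operator
splitting: the cell model advances at `dt_reaction` (0.02 ms) and an
explicit diffusion update `V <- V + dt_diffusion * (L V)` at
`dt_diffusion` (0.1 ms). `L` is a 9-point anisotropic finite-difference
operator built from the local fiber angle and the longitudinal/transverse
diffusion coefficients: direct-neighbor weights use edge-wise harmonic
means (zero across scar faces, which makes scar interfaces exactly
flux-free), and the mixed-derivative terms are dropped within one node of
any non-conducting node or the grid edge so that every row sums to zero —
the discrete form of charge conservation under no-flux boundaries. Scar
and outside nodes carry no state at all; they render as `NA` in exported
frames.

Defaults: dx 0.25 mm, D_l 1.0e-3 cm^2/ms and D_t = D_l/6.25, tuned to
give a longitudinal conduction velocity near 60 cm/s and transverse near
24 cm/s on the default grid; border-zone transverse conductivity is
further multiplied by 0.25 (a slow-conduction substrate). Conduction
velocity under these discretizations converges slowly (roughly 2% change
per halving of dx near the default spacing); since the diffusion
coefficients are calibrated to the target velocity at the operational
resolution, this affects absolute CV accuracy, not the comparisons the
study makes, and the refinement behavior is itself under test at finer
spacings.

Stimuli are cathodal current discs (default radius 1 mm, 2 ms); when no
amplitude is configured, protocols resolve it once per configuration as
twice the diastolic threshold found by a doubling search with a
propagation check. Voltage movies store frames at a configurable stride
(2 ms for analysis runs — activation-time interpolation needs <= 2 ms)
plus dense probe traces, and carry the full final state so protocols can
checkpoint and chain runs. Chained segments reproduce an unchunked run
bit-for-bit: all segment lengths are multiples of the diffusion step and
stimulus windows carry a 1e-6 ms slack so floating-point differences in
the time origin cannot shift a stimulus by one step.

# Programmed stimulation

`run_ets()` delivers the S1 drive train (six stimuli by default), then
searches the premature coupling upward from (refractory estimate - 50 ms)
in 5 ms steps, restarting each trial from the saved pre-stimulus state;
the refractory estimate is the single-cell APD90 of the pacing site's
tissue class at the drive-train rate, which tracks the local tissue ERP
closely at these rates. Capture demands an upstroke at the pacing site
within 15 ms of the stimulus *and* a sentinel upstroke at >= 5 mm within
a distance-consistent window (so a local-only depolarization does not
count); in the single-node limit the site criterion alone decides, which
is what the ERP probe's exhaustive-scan oracle exercises. After each
captured premature stimulus the simulation runs stimulus-free for the VT
check window (default 2 s); only if no reentry survives does the protocol
escalate to S3 and then S4, each riding on its captured predecessors.
Detected VTs are recorded over a longer horizon (default 4 s).
`run_xts()` replays explicit couplings; a non-capturing premature
stimulus is still delivered as a field stimulus and flagged.

Reentry is defined as at least two reentrant cycles. The detector
operationalizes this as: at least two stimulus-free activations on a
spatially spread node set (>= 5% of conducting nodes reaching the count,
>= 10% activated at all), plus loop closure, operationalized as phase
coverage — within the dominant cycle (median inter-activation interval),
activation times must occupy at least 75% of 16 phase bins. A circulating
wavefront activates tissue at every phase of its cycle; a repetitive
focal source clusters in a narrow phase band and is rejected. The
post-stimulus observation windows (2 s check / 4 s horizon) are package
choices; nothing external fixes them.

# Circuit analysis

Activation maps interpolate -40 mV upward crossings between frames. For
an analyzed VT the package picks a late full cycle, finds the exit time —
the earliest activation of normal tissue causally fed (activation-time
increasing, 8-adjacent) from border-zone/channel tissue — and re-anchors
the cycle window to end exactly there; the 8 isochrones are then
equal-width bins of that window, so bin 8 ends at the circuit exit (the
gray-to-purple convention, purple latest). Block lines are chains of
adjacent activated node pairs whose *circular* activation-time difference
(modulo the cycle) exceeds 30% of the cycle length; the circular
difference discards the head-tail wrap of any windowed activation
sequence while keeping true block, where tissue on the two sides of a
line activates about half a cycle apart. Exit-site candidates cluster by
adjacency, and every cluster whose earliest time falls within an eighth
of the activation range of the global earliest forms an exit (so
two-mouth channels report two exits). The reentry pathway is traced from
the latest-activated node by following, at each step, the neighbor with
the smallest positive circular activation-time increment, with a bias
toward nodes hugging scar/border-zone tissue, until the walk closes on
its start; the traversal sense is the sign of the closed polygon's area.
Morphology is `double_loop` when the pathway runs through a corridor
flanked by two distinct scar components (the figure-of-eight signature),
`single_loop` when it encircles one obstacle, `other` otherwise.

Circuits are compared with declared, configurable thresholds (the source
criteria are qualitative): pathways match when the Jaccard overlap of
their dilated pathway masks reaches 0.7 *and* both loops share a
traversal sense (a reversed loop on the same channel — reversed entrance
and exit — is not a match); exit sites match when the minimum pairwise
distance is within a 5 mm concordance radius. All thresholds are reported
alongside results.

# Cross-model statistics

Fisher's exact test is computed from first principles with
log-factorials: the two-sided p-value sums the hypergeometric
probabilities of all margin-preserving tables whose point probability
does not exceed the observed one (relative slack 1e-7) — the conventional
point-probability rule. The test suite checks it against exhaustive
enumeration for every 2x2 table with total up to 40. `build_match_matrix()`
collapses the per-VT match states into 2x2 tables per variant contrast
(baseline vs ab_tm, baseline vs ab_only, baseline vs tm_only, ab_tm vs
ab_only, ab_tm vs tm_only): pathway/exit tables put the two protocol
modes (ETS, XTS) in rows when both are present — the convention that
reproduces published counts of the form "3/6 vs 2/7 -> [[3,3],[2,5]]" —
and the two variants otherwise; inducibility tables count induced versus
non-induced attempts per variant. Because the cell construction for
inducibility is not externally fixed, the per-attempt convention is the
default and the per-VT state matrix is always reported alongside.

# Desk-scale fixtures and what they do (not) show

The reduced test substrates live on a 96 x 96 sheet at dx 0.25 mm
(2.4 cm) and use a dedicated configuration: isotropic D = 2.5e-4 cm^2/ms
(conduction velocity ~ 23 cm/s), normal cells with I_Ks x 6 and I_CaL x
0.5 (APD90 ~ 138 ms at CL 300 ms), border-zone cells with the standard
remodeling on top (~ 176 ms). These values were chosen once so that the
reentrant wavelength (~3 cm) fits the sheet; they are not the study
conditions of the full-scale model, and passing fixture tests shows that
the operators behave correctly, not that a 2.4 cm sheet is a ventricle.

* The annulus fixture confines conduction to a ring corridor (scar disc
  inside, scar outside, conducting ring r = 8–11 mm), so the circulation
  time has a closed form, perimeter / CV; the measured cycle length
  agrees within 15% (observed ~5%).
* Reentry is initialized there by a phase-ramp ("virtual wave history")
  state: nodes carry single-cell states aged linearly behind the
  wavefront head, with the oldest age beyond full repolarization so the
  tail blends into resting tissue. A naive two-zone excited/refractory
  initialization consistently self-destructs — the refractory flank
  recovers beside still-depolarized tissue and launches a retrograde
  wave — which is why the ramp initializer is the supported interface.
* The figure-of-eight fixture (two scar blobs, border-zone channel)
  genuinely induces VT through the programmed-stimulation machinery: the
  premature stimulus blocks in the long-APD channel, rounds both scar
  lobes, and re-enters retrogradely (a double-loop VT of ~270 ms cycle
  length after up to three premature stimuli).
* The shortened-AP medium itself is spiral-capable: on a bare sheet large
  enough relative to its reduced wavelength, an aggressively timed
  premature train can start *functional* reentry with no substrate at
  all. The no-substrate/no-reentry control therefore runs with
  unmodified cells, whose wavelength far exceeds the sheet; the package
  treats substrate-free functional reentry as real model behavior, not a
  detector artifact.

What the synthetic substrates do **not** emulate: real ventricular
anatomy and wall thickness, intramural circuit geometry (a 2D sheet
cannot express transmurally layered circuits; the slab3d geometry flag is
reserved and errors), rate-dependent restitution heterogeneity beyond the
two tissue classes, Purkinje involvement, and autonomic modulation beyond
its I_Ks endpoint.

# Numerical choices and degenerate inputs

* Reaction dt 0.02 ms (max 0.05), diffusion dt an integer multiple;
  voltage outside [-120, 95] mV raises an instability error naming time
  and node; a non-finite state names the first offending variable.
* The gate lookup tables are keyed to dt and rebuilt on change; step
  halving moves single-step voltage by < 0.01 mV and APD90 by < 0.5 ms.
* Bisection tolerance for the I_Ks calibration is 1 ms on the APD; the
  multiplier bracket is [0.1, 10] and targets outside the achievable
  range report the bracket.
* Zero scar targets produce clean all-normal sheets; an all-zero match
  table is an undefined Fisher test and errors; ties in the scar score
  threshold are resolved by the quantile rule (a node count may exceed
  the target by the tie multiplicity).
* Problem sizes used by the shipped tests: single-cell runs up to 50
  beats; tissue fixtures 96 x 96 (analysis) and 36–48 squared (protocol
  scans); induction horizons 0.5–1.5 s on fixtures. The full-scale
  defaults (192 x 192, 2 s / 4 s windows, six S1) are the package's
  standing configuration for real experiments.

# Known limitations

* The inducibility of *generated* substrates under the full protocol grid
  is substrate-dependent; the shipped experiment scripts demonstrate the
  workflow on the inducible fixture rather than claiming population-level
  inducibility statistics.
* Pathway tracing is a greedy local walk; on highly irregular activation
  maps it can take shortcuts a human tracer would not. The comparison
  operators treat the traced pathway as a mask, which keeps the match
  decision robust to small tracing differences.
* Conduction velocity converges at roughly first order in dx around the
  default spacing, so D is calibrated at the operational resolution
  rather than extrapolated to the continuum.
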