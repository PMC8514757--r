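# vtgrad

Desk-scale in-silico study of how apicobasal (AB) and transmural (TM)
repolarization gradients alter post-infarct ventricular tachycardia (VT)
dynamics — inducibility, reentrant pathway, and exit site.

## Who this is for

Computational cardiac electrophysiologists and arrhythmia researchers who
want a self-contained, reproducible 2D testbed for scar-related reentry
under programmed electrical stimulation, with physiological repolarization
gradients imposed through the slow delayed rectifier potassium current
(I_Ks) — the current through which sympathetic tone shapes regional
repolarization.

## The model in brief

* **Membrane**: ten Tusscher–Panfilov (2006) human ventricular myocyte
  (epicardial set), Rush–Larsen gates + forward Euler, with an infarct
  border-zone variant (g_Na ×0.38, g_CaL ×0.31, g_Kr ×0.30, g_Ks ×0.20)
  and a multiplicative I_Ks hook.
* **Gradients**: the AB coordinate u_ab is the geodesic distance from the
  base normalized to [0,1]; the TM coordinate u_tm solves ∇²u = 0 with
  endocardium = 0, epicardium = 1 and no-flux on scar. I_Ks is scaled by
  f = (1 + 0.5 u_ab)(1 + 0.5 u_tm) for the combined AB-TM variant, i.e.
  1 at the basal endocardium up to 2.25 at the apical epicardium; single
  axes span [1, 1.5]. Calibrated so APD₉₀(scale 1) = 303 ms at cycle
  length 600 ms; scales 1.5 and 2.25 then shorten APD₉₀ toward the 272
  and 242 ms landmarks (measured ≈ 276 and ≈ 249 ms).
* **Tissue**: anisotropic monodomain reaction–diffusion on a sheet whose
  axes read base→apex and endo→epi, with non-conducting scar,
  slow-conducting border zone, conducting channels, fibers, and
  "RV-apex analog" pacing sites; synthetic substrates reproduce cohort
  statistics (scar 12.6 %, border zone 6.8 % of myocardium).
* **Protocols**: S1 drive trains (BCL 600 / 350 ms) plus up to three
  premature stimuli, either re-timed at the earliest capturing interval
  (ETS) or replayed verbatim from a baseline induction (XTS). VT = at
  least two reentrant cycles.
* **Analysis**: activation maps, 8 isochrones anchored at the circuit
  exit, conduction block lines, exit sites, pathway tracing and
  cross-variant circuit comparison; Fisher's exact test (computed from
  first principles) on the match/no-match tables.

See `vignettes/repolarization-gradients.Rmd` for the full methods
account, parameter defaults, and limitations.

## Worked example

Calibrate the I_Ks anchor and read off the gradient APD chain:

```r
library(vtgrad)
cal <- calibrate_base_gks(303, pacing_cl = 600, tol = 1)
cal
#> [1] 0.8976871
apd_sweep(c(1, 1.5, 2.25), base_gks_calibration = cal)
#>   iks_scale pacing_cl apd90_ms
#> 1      1.00       600 303.0483
#> 2      1.50       600 276.1809
#> 3      2.25       600 249.2375
```

APD₉₀ shortens from the 303 ms anchor to ≈ 276 ms at scale 1.5 and
≈ 249 ms at 2.25 — the apicobasal/transmural repolarization gradient the
tissue models impose spatially.

Generate a substrate and induce VT on the shipped figure-of-eight
fixture:

```r
d <- generate_substrate(substrate_params(rng_seed = 1))
d
#> <tissue_domain> 192 x 192 nodes @ 0.25 mm | scar 12.6%, border zone
#>   6.8% of myocardium | 2 scar component(s), 1 channel(s), 3 pacing
#>   site(s)

dom <- fixture_fig8()
cfg <- fixture_sim_config(stim_amp = -40)
out <- run_ets(dom, NULL, cfg, site_index = 2, bcl = 350, s1_count = 4,
               vt_check_ms = 1500, vt_horizon_ms = 1500)
out
#> <induction_outcome> ETS site 2 BCL 350 | couplings 180/215/150 |
#>   VT: induced (6 cycles, CL 272 ms), post-stimulus activity 1498 ms

circ <- analyze_vt(out, dom)
circ
#> <vt_circuit> double_loop reentry | 6 cycles, CL 272 ms |
#>   4 block line(s), 1 exit site(s), pathway 370 nodes
```

The premature stimuli block in the long-refractory border-zone channel,
round both scar lobes, and re-enter retrogradely — a figure-of-eight VT
whose cycle length, isochrones, block lines, and exit site the analysis
extracts automatically.

The end-to-end study (substrates → fields → inductions → circuits →
statistics) is driven by the numbered scripts under `analysis/`, which
write their tables to `results/`.

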