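#!/usr/bin/env Rscript
# Run the cross-variant experiment grid on the inducible figure-of-eight
# substrate: baseline and AB-TM gradient models, ETS induction plus XTS
# replay of the baseline-inducing protocol, then per-VT circuit
# comparison. Desk scale: one substrate, one pacing site, BCL 350 ms.
# The run is resumable; rerunning skips completed cells.

library(vtgrad)
dir.create("results", showWarnings = FALSE)

cfg <- experiment_config(
  domains = list(fixture_fig8()),
  sim = fixture_sim_config(record_stride = 2, stim_amp = -40),
  variants = c("baseline", "abtm"),
  sites = 2, bcls = 350, modes = c("ETS", "XTS"),
  s1_count = 4, vt_check_ms = 1500, vt_horizon_ms = 1500,
  out_dir = "results/experiment", master_seed = 1L)

res <- run_experiment(cfg)
print(res$manifest)
if (!is.null(res$summary)) print(res$summary)
message("manifest: results/experiment/manifest.csv (config hash ", res$hash, ")")
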