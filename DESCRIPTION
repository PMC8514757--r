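Package: vtgrad
Title: Post-Infarct Ventricular Tachycardia Dynamics Under Apicobasal and
    Transmural Repolarization Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale in-silico study of how apicobasal and transmural
    repolarization gradients alter post-infarct ventricular tachycardia (VT)
    dynamics. Provides a human ventricular ionic cell model (ten
    Tusscher-Panfilov 2006) with infarct border-zone remodeling and an I_Ks
    conductance hook, a synthetic 2D infarct substrate generator (scar, border
    zone, conducting channels, fibers, pacing sites), geodesic apicobasal and
    Laplace transmural coordinate fields, an anisotropic monodomain
    reaction-diffusion solver, programmed electrical stimulation protocols
    (S1 drive trains with earliest-timed and exact-timed premature stimuli),
    VT circuit analysis (activation maps, isochrones, block lines, exit
    sites), and Fisher's exact test computed from first principles for
    cross-model comparisons.
License: MIT
Encoding: UTF-8
Imports:
    tools,
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
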