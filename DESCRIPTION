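Package: cryodrag
Title: Thermal Control of Spiral and Scroll Waves in Simulated Atrial Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation framework for temperature-based control of reentrant
    excitation waves in human atrial tissue. Couples a temperature-sensitive
    Courtemanche-Ramirez-Nattel ionic model (Q10 scaling of gating kinetics,
    chronic atrial fibrillation remodeling) to a monodomain reaction-diffusion
    solver in 1D/2D/3D and a bioheat conduction solver with movable cold-spot
    Dirichlet sources. Provides S1-S2 cross-field reentry induction,
    phase-singularity and scroll-filament tracking, action-potential metrology,
    and the attract-anchor-drag protocol that relocates a spiral or scroll
    wave to an inexcitable boundary for termination.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
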