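Package: poregate
Title: Gating Order Parameters and Ensemble pKa Estimation for Ion-Channel Pore Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing of molecular-dynamics ensembles of tetrameric
    potassium-channel pore domains. Computes per-frame gating order
    parameters (cavity water count, S6 kink dihedral, inter-subunit
    nearest-atom distance) from multi-model PDB trajectories, pools windowed
    ensembles into distributions, mode sets, log-population heat maps and
    order-parameter correlations, and reconstructs the pH-dependent
    partition function over protonation microstates from per-structure
    energy tables to estimate per-site pKa values with structural-fluctuation
    uncertainty bands. A synthetic two-state toy-channel generator with
    known ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
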