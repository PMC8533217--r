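Package: mdscape
Title: Free-Energy Landscapes, Conformer Statistics and Pocket Volumes
    from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Population-based analysis of molecular dynamics trajectories
    of the stearoyl-CoA desaturase-1 (SCD1) binding tunnel and similar
    systems: paired hydrogen-bond-distance free-energy landscapes in kT
    units via Boltzmann inversion of binned populations, dihedral
    distributions and free-energy profiles with gauche/trans conformer
    classification, conditional conformer statistics given a geometric
    hydrogen-bond criterion, and grid-based spherical pocket-volume
    measurement. Includes a two-state Markov-chain generator of
    ground-truth-labelled synthetic trajectories for end-to-end testing,
    and readers/writers for multi-model PDB and DCD trajectory formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    grDevices,
    graphics,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
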