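Package: chromapore
Title: Interfacial Analysis of Solvated Reversed-Phase Chromatographic Slit Pores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for particle configurations of solvated
    reversed-phase liquid chromatography (RPLC) slit-pore systems: species
    density profiles against distance from the silica surface, bonded-phase
    contact statistics and the stationary-phase limit, distance-criterion
    solute-solvent hydrogen-bond detection (including pi hydrogen bonds),
    hydrogen-bond partner density profiles, analyte orientation analysis,
    and molecular-graph solute descriptors (group-contribution van der Waals
    volume, hydrophobic CH_x group counts, retention and selectivity
    arithmetic). Ships a synthetic slit-pore configuration generator with
    fully known ground truth so every estimator is testable without
    molecular-dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
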