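Package: halokin
Title: Kinetic and Structural Characterization Toolkit for Halophilic Dehydrogenases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational characterization of halophilic
    NAD(P)-dependent dehydrogenases such as the short-chain glucose-6-phosphate
    dehydrogenase of Haloferax volcanii. Fits Michaelis-Menten kinetics to
    initial velocities and derives catalytic efficiencies across salt
    conditions; sizes the auxiliary enzyme of a two-enzyme coupled assay from
    the coupled-reaction differential equation (Storer-Cornish-Bowden design)
    with correction for promiscuous background activity; computes
    solvent-accessible surface area by the Shrake-Rupley method and classifies
    residues into exposed and core shells for haloadaptation composition
    statistics; re-implements standard molecular-dynamics trajectory
    observables (Kabsch superposition, RMSD, RMSF, radius of gyration, and
    selection-pair Coulomb and Lennard-Jones interaction energies); scans
    protein sequences for wildcard motifs; and generates seeded synthetic
    datasets for every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
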