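Package: sheetmem
Title: Coarse-Grained Modelling of MoS2 Nanosheet Insertion into Lipid Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how surface aging of molybdenum disulfide
    (MoS2) nanosheets changes their interaction with lipid bilayer
    membranes. Provides a parameterized triangular-nanosheet builder with
    fresh and aged force-field states calibrated from water contact angles,
    a seeded overdamped-Langevin simulator of sheet-membrane approach and
    insertion against implicit and bead-explicit bilayers, an umbrella
    sampling driver with a from-scratch weighted histogram analysis method
    (WHAM) solver for potentials of mean force, and the standard trajectory
    statistics of membrane-insertion studies: atom contacts, head/tail
    contact splits, bound-water counts, centre-of-mass insertion depth,
    van der Waals and Coulomb energy decomposition, acyl-chain order
    parameters, membrane thickness and insertion-time detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
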