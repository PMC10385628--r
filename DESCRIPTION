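Package: contactzones
Title: Hirshfeld Interface Contacts, Enrichment Ratios and Electrostatic
    Influence Zones for Protein-Ligand Complexes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of protein-peptide interfaces from atomic models:
    construction of the Hirshfeld interface between two molecular moieties on
    spherical (promolecule) electron densities, with a solvent-exposure density
    cutoff; chemical-type contact statistics (surface compositions, contact
    proportions, equiprobable random contacts and enrichment ratios, including
    a hydrophobic/hydrophilic grouping); nucleophilic influence zones mapped by
    tracing electric field lines of a point-charge model to their attracting
    basins; and fluctuation analytics (Kabsch superposition, RMSD series,
    RMSF profiles, root mean square thermal displacements from crystallographic
    B factors). Seeded synthetic generators provide toy complexes, random-mixing
    null fixtures, point-charge systems and Gaussian ensembles so that every
    stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
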