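Package: gaqsar
Title: GA-MLR QSAR Modelling and Trajectory Post-Analysis for
    Acetylcholinesterase Inhibitor Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and validates genetic-algorithm multiple-linear-regression
    (GA-MLR) quantitative structure-activity relationship (QSAR) models for
    acetylcholinesterase inhibition. Computes the five descriptor families of
    the published five-term model (longest pi-conjugation path, Moran
    autocorrelation weighted by Kier-Hall intrinsic states, GETAWAY R
    autocorrelation weighted by mass, carbamoyl/urea fragment counts, and
    multilevel-neighborhood-of-atoms substructure counts) from SMILES or SDF
    input; pre-filters descriptor pools; selects descriptor subsets by a
    seeded genetic algorithm with leave-one-out cross-validated fitness; and
    evaluates models with the OECD statistics suite (Q2 leave-one-out and
    leave-many-out, Lin's concordance correlation, predictive R2, rm2
    metrics, Y-randomization, and the Williams-plot applicability domain).
    Also provides formula-level molecular-dynamics post-statistics (Kabsch
    superposition, RMSD, RMSF, radius of gyration, dynamic cross-correlation
    matrices, principal-component modes, and Boltzmann-inversion free-energy
    landscapes) and seeded synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    ChemmineR,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineOB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
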