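Package: dualscreen
Title: Dual-Target Inhibitor Screening from Bioactivity Data, Interaction
    Fingerprints, QSAR and Trajectory Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering candidate dual-target enzyme
    inhibitors (such as joint EZH2 / proteasome-20S modulators) from public
    bioactivity data. Implements bioactivity record curation with unit
    normalisation and three-class activity binning; chemical-space comparison
    of two inhibitor sets (physicochemical profiles, Bemis-Murcko scaffolds,
    cross-set Tanimoto similarity, maximum common substructures, 2-D
    embedding); a protein-ligand interaction fingerprint (PLIF) similarity
    screening model with enrichment-curve optimisation over residue subsets
    and a dual-target hit criterion; a weighted three-class decision-tree
    QSAR harness with applicability-domain flagging; molecular-dynamics
    post-analysis statistics (energy drift, RMSF, minimum distances,
    hydrogen-bond occupancy); and seeded synthetic-data generators so every
    stage can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    rpart,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
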