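Package: pharmfunnel
Title: Consensus 3D Pharmacophore Models and Two-Stage Virtual Screening Funnels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds structure-based consensus pharmacophore hypotheses from sets
    of prealigned ligands by clustering perceived chemical features (hydrogen-bond
    acceptors and donors, hydrophobic groups, aromatic rings) and retaining
    consensus sites supported by a minimum fraction of the ligands. Screens
    compound libraries against a hypothesis in a two-stage funnel: a
    conformer-ensemble alignment screen (correspondence-graph clique search with
    Kabsch superposition) before docking, and an in-place tolerance-sphere
    rescreen of externally produced docking poses after. Also enumerates
    combinatorial amide libraries from carboxylic-acid scaffolds and amine
    building blocks with Lipinski drug-likeness filtering, and ships a
    synthetic-data generator for planted hypotheses, jittered ligand feature sets
    and verified decoys.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
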