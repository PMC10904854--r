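Package: switchtile
Title: Peptide-Tiling Screens for Ligand-Induced Conformational Switches in
    Disordered Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to screen intrinsically disordered protein sequences for
    conformational-switch regions by tiling the sequence into peptides and
    comparing conformational ensembles between a reference condition (water)
    and a perturbed condition (hydrophobic probe or bound ligand). Provides
    sequence tiling, hydropathy and disorder profiling, peptide-mass and m/z
    utilities, readers and writers for multi-model PDB and XYZ ensembles,
    radius-of-gyration distributions and a quantitative switch decision rule,
    an MM/GBSA enthalpic and binding energy model with per-residue
    decomposition, ligand-residue contact scoring with contact-fingerprint
    pose clustering, an orientation-averaged projection-approximation
    collision cross section calculator, and a seeded pivot Monte Carlo
    generator of two-state compact/extended bead ensembles for testing every
    stage without molecular dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
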