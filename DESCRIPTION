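Package: ifacetools
Title: Interface Analysis of Docking-Pose Ensembles, Trajectories and
    Binding Titrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tidy toolkit for the structural and biophysical analysis of
    protein-protein docking pose ensembles and molecular-dynamics output.
    Computes per-residue interface contact prevalence across docked poses
    with symmetry folding for homodimeric receptors, domain localization of
    binding sites, interface RMSD against an average complex with funnel
    diagnostics, trajectory RMSD traces, equilibration detection and
    per-residue RMSF with proximal/distant comparisons, lineage-specific
    interface residue calling from multiple sequence alignments, pairwise
    percent identity and isoelectric points, and equilibrium binding-curve
    fits (ligand-depletion single-site, Hill, competitive displacement) plus
    coupled-assay rate conversion. Includes seeded synthetic-data generators
    with planted ground truth for every input class so the full pipeline is
    testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
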