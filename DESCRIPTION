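Package: minidock
Title: Deterministic Matching-Sphere Docking with Grid Scoring and
    Enrichment Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A compact molecular docking core built around deterministic,
    regularly variable sampling of ligand orientations by clique matching of
    rigid-component heavy atoms onto receptor matching spheres with an
    adaptive distance tolerance; trilinear-interpolated scoring of
    multi-conformer ligand hierarchies on precomputed energy grids (van der
    Waals, electrostatic, ligand desolvation) with a repulsive van der Waals
    bump filter; and the virtual-screening evaluation metrics used to
    benchmark such engines (ROC AUC, adjusted logAUC, enrichment factors,
    and symmetry-corrected RMSD by optimal assignment).  Ships TRIPOS mol2
    and a documented multi-conformer hierarchy ("db2-lite") reader and
    writer, aromatic/aliphatic hydroxyl rotamer resetting, conformer
    energy-window filtering, and seeded synthetic fixture generators so the
    whole engine is exercisable with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
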