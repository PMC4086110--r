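Package: cadscorer
Title: Contact Area Difference Scoring of Macromolecular Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Superposition-free comparison of 3D structures of proteins,
    nucleic acids and their complexes using the Contact Area Difference
    score (CAD-score). Residue-residue contact areas are derived from a
    Voronoi-style partition of solvent-expanded atomic spheres; global
    scores and per-residue local error profiles are computed for
    whole structures, inter-chain interfaces and custom residue
    selections, with atom-subset variants (all/main-chain/side-chain,
    backbone/base, base stacking). Includes a PDB reader/writer,
    deterministic synthetic structure generators for testing, and
    tabular and raster reporting of scores, error profiles and
    superimposed contact maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
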