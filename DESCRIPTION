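Package: sitematch
Title: Fast Rigid-Body Matching of Ligand Binding Sites into Protein Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing whether known ligand binding site geometries can
    be engineered into protein backbone scaffolds. Implements a fast rigid-body
    matching protocol (anchor-residue superposition, nearest-residue
    correspondence, backbone RMSD, CA-CB direction cosine and steric clash
    gates), construction of binding-site libraries from PDB structures with a
    pluggable interaction-score proxy, side-chain-independent burial layer
    assignment and depth scores, Butina clustering of ligands by 3D
    fingerprints, matchability statistics (encounter curves, power-law scaling,
    overlap tests, subset resampling), a geometric-constraint file writer for
    an external matcher, and deterministic synthetic fixture generators
    (idealized backbones, planted binding sites, match matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
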