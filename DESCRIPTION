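Package: homomod
Title: Template-Based Protein Structure Modelling with Quality Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained comparative (homology) modelling pipeline for
    protein tertiary and quaternary structure. Builds an annotated template
    library from PDB/mmCIF files organized by biological assemblies with
    two-stage ligand classification, searches it with an affine-gap local
    aligner, ranks templates by a global model quality estimate (GMQE)
    obtained by maximizing joint probability densities of alignment features,
    builds all-atom models by coordinate transfer including homo-oligomeric
    copies and conserved ligands, predicts interface conservation with a
    random forest, and estimates model quality with statistical potentials of
    mean force (per-residue reliability scores in [0,1], global scores and
    Z-scores). Models are evaluated against references with a
    superposition-free local Distance Difference Test (lDDT) and Kabsch
    superposition. Includes a deterministic fixture generator for toy folds,
    homolog pairs, complexes, decoys and calibration benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
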