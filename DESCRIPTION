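Package: apophore
Title: Receptor-Based Pharmacophore Generation and Screening Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates ligand-independent (apo-capable) pharmacophore models
    directly from a protein binding pocket. Probe maps over a pocket grid are
    filtered by score thresholds, same-type neighbour counts and 2.5 Angstrom
    non-maximum suppression; complementary interaction sites are projected
    from pocket residues using SP2/SP3 hybridization cone geometry; aromatic
    ring features are detected from ring-normal orientation; and the
    surviving point sets are merged under a 3 Angstrom constraint into a
    six-type pharmacophore. Includes a triangle-hash pharmacophore/ligand
    matcher and virtual-screening evaluation (ROC AUC, enrichment factors),
    plus deterministic synthetic pocket and ligand-library generators for
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
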