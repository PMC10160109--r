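Package: smexplain
Title: Substructure-Mask Explanation for Molecular Graph Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits consensus relational graph convolutional network (RGCN)
    models for molecular property prediction from SMILES, and explains their
    predictions at the level of chemically meaningful substructures by
    masking fragments at the attention-pooled readout and measuring the
    change in the consensus prediction. Molecules are decomposed with BRICS
    retrosynthetic rules, Bemis-Murcko scaffold/side-chain splitting, and a
    configurable functional-group SMARTS catalog. On top of the attribution
    engine the package provides dataset-level functional-group attribution
    tables, cross-property attribution correlation, substituent scanning,
    attribution-guided structural optimization suggestions, and
    attribution-based BRICS fragment recombination for molecule generation.
    A self-contained synthetic-data module generates SMILES libraries with
    known additive group-contribution labels or toxicophore-defined binary
    labels so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
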