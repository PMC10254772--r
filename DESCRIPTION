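Package: condsmiles
Title: Conditional Transformer Generation of Target-Specific Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: A decoder-only Transformer language model over SMILES strings
    that generates drug-like molecules either unconditionally or conditioned
    on a protein-target embedding injected as the keys and values of a
    dedicated attention sublayer. Provides next-token pre-training on
    unlabeled SMILES corpora, target-conditional fine-tuning on
    compound-target pairs, autoregressive temperature sampling, the standard
    generative-chemistry evaluation metrics (validity, uniqueness, novelty,
    fragment similarity, nearest-neighbour similarity, property
    Wasserstein-1 distances, drug-likeness profiling), and a
    gradient-boosted QSAR activity model over fingerprint and descriptor
    features. Chemistry (parsing, canonicalization, fingerprints,
    descriptors) is delegated to RDKit through a batched Python bridge; the
    model, training, and sampling are implemented natively.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    data.table,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with rdkit, numpy, scikit-learn, joblib
    available on the PATH as 'python'
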