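Package: mctsmol
Title: Reward-Guided Monte Carlo Tree Search Generation of Drug-Like Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A de novo molecule generation engine that decodes a conditional
    autoregressive SMILES language model with a reward-guided Monte Carlo Tree
    Search, alongside greedy and beam-search baselines. A protein-sequence
    encoder conditions a SMILES decoder; search rewards enforce chemical
    validity, Lipinski's Rule of Five, QED drug-likeness and, optionally,
    docking affinity through an external-program adapter. Includes
    BindingDB-style record filtering and train/test splitting, a synthetic
    protein-ligand fixture generator, and distribution-learning evaluation
    metrics (validity, uniqueness, novelty, mean QED). Chemistry primitives
    (parsing, canonicalization, descriptors, QED) are delegated to an RDKit
    worker process.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
SystemRequirements: Python (>= 3.8) with the rdkit package, available as
    'python' on the PATH (configurable via option mctsmol.python).
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
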