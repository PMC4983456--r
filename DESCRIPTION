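Package: pipeppi
Title: Interaction-Pattern-Tree Kernel Extraction of Protein-Protein
    Interaction Passages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines frequent protein-protein interaction (PPI) patterns from
    semantic-class sequences of biomedical sentences, represents each
    candidate protein pair as an interaction pattern tree (IPT) derived from
    the shortest-path-enclosed constituency tree, and classifies pairs as
    interacting or not with a convolution subset-tree kernel and a
    max-margin classifier.  Includes readers and writers for a minimal
    BioC-style XML dialect, Penn-bracketed parse trees, CoNLL-like typed
    dependencies and trigger-word lexicons, a seeded synthetic corpus
    generator with template-derived parses for fully offline testing, and
    cross-validation, cross-learning and cross-corpus evaluation protocols
    with precision/recall/F1 and micro-averaged summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    kernlab,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
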