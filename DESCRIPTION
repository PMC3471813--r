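Package: genelit
Title: Assigning Genes to Functional Categories by Literature Profiling
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Represents each gene as a term-frequency vector built from its
    MEDLINE abstract corpus, discloses the minimum informative vocabulary by
    filtering promiscuous and gene-specific stemmed terms against a baseline
    corpus, collapses near-duplicate literature profiles, and trains a
    confidence-scored multiclass support vector machine that assigns genes to
    functional categories of a JCVI-CMR-style ontology. Includes the full
    replicated-holdout evaluation protocol with confidence-thresholded
    precision/recall curves, a category-structured synthetic corpus generator
    with known ground truth, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
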