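Package: nucleoclass
Title: Four-Class Prediction of Protein Nucleolar Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies human proteins into four degrees of nucleolar
    association (nucleolar-enriched, nucleolar-nucleoplasmic,
    nucleolar-cytoplasmic, non-nucleolar) by integrating five discretized
    feature channels (amino-acid frequencies, targeting-motif predictions,
    gene co-expression, Gene Ontology annotation scores, and the nucleolar
    proximity of interaction partners) in a semi-naive Bayes model with a
    reliability index. Includes leave-one-out cross-validation with
    interactor-leakage guards, multi-run evaluation over resampled negative
    sets, mapping of dual SILAC abundance ratios onto the four classes,
    Gene Ontology term censuses with descendant closure, bootstrap estimates
    of orthologue-conservation fractions, and a synthetic cohort generator
    with class-conditional structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
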