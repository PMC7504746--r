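Package: lwas
Title: Literature-Wide Association Studies for Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the Literature-Wide Association Study (LWAS) approach
    to drug repurposing. Biomedical abstracts are cleaned, sentence-split and
    tokenized with multiword drug and disease names collapsed to single
    hyphenated tokens; a shallow neural word-embedding model (CBOW or
    skip-gram with negative sampling) is trained on the corpus; diseases
    similar to a target disease are retrieved by cosine similarity in the
    embedding space; and the known drugs of those similar diseases, taken
    from a curated drug-disease reference set, are proposed as repurposing
    candidates and evaluated against a literature annotation table. Includes
    exact t-SNE similarity maps with a trustworthiness diagnostic and a
    synthetic-corpus generator with planted disease groups for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
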