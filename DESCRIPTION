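Package: fundaudit
Title: Auditing Funding-Acknowledgement Transparency in Bibliographic Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit how completely a research funder's published
    transparency lists cover the literature that acknowledges its funding.
    Screens bibliographic records for direct funder acknowledgement through a
    conserving PRISMA-style ledger, rebuilds a funded-author cohort under
    disclosure-list eligibility rules, matches inconsistently rendered author
    names to transparency lists by exact and approximate string matching,
    quantifies disclosure coverage and survey-based adjustments, and
    characterises the funded literature by weighted co-authorship networks
    (Girvan-Newman edge-betweenness communities) and latent topic models of
    abstracts. Includes a synthetic-corpus generator with planted ground truth
    so every stage is testable without proprietary database access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
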