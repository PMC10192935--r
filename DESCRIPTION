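Package: msdblink
Title: Cross-Database Reconciliation of U.S. Mass-Shooting Incident Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Harmonizes heterogeneous incident-level exports from five U.S.
    mass-shooting surveillance databases (the FBI Supplementary Homicide
    Report and Active Shooter Report, Mother Jones, Everytown for Gun Safety,
    and the Gun Violence Archive), encodes each database's inclusion
    definition as declarative, evaluable criteria, links records that
    describe the same real-world incident across sources (blocking, pairwise
    similarity scoring, threshold classification, and transitive clustering
    with a manual-review queue), and computes per-database summary tables and
    exclusive set-intersection (UpSet) overlap counts, including
    case-definition sensitivity re-analyses under a common fatality
    threshold. A synthetic five-source generator with full ground truth makes
    every stage testable without the live databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
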