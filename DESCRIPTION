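Package: ctassoc
Title: Disease-Target Association Scoring from Aggregated Clinical-Trial Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers and ranks associations between diseases (Disease Ontology
    identifiers) and protein-coding gene targets from registry-style clinical
    trial evidence tables. Joins interventional drug studies with drug-target
    and study-disease annotations into per-association evidence rows, computes
    six evidence metrics per disease-gene pair (including a recency-decayed
    study-newness score and a reference-type-weighted publication score),
    aggregates the metrics into a 0-100 mean-rank score, emits full trial and
    publication provenance, and validates association sets against an external
    disease-gene reference through DOID-to-UMLS-CUI crosswalks. Includes a
    seeded generator of registry-shaped synthetic evidence tables with planted
    associations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
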