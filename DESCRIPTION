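Package: hipnet
Title: Huntingtin Interactome Catalogs, Metadata Filtering, and IP-MS Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a human-ortholog-centric catalog of huntingtin (HTT)
    protein-protein interaction reports together with multi-omics
    measurements from polyglutamine allelic-series mouse models, filters
    interactions by experimental metadata with AND/OR/NOT operators,
    constructs STRING-scored functional networks over the filtered genes,
    overlays bulk and single-cell omics with bounding envelopes and
    fold-change highlights, performs Fisher-exact overrepresentation
    analysis with FDR control, registers user interaction datasets and
    classifies their overlap with the catalog, and implements downstream
    scoring of immunoaffinity-purification mass spectrometry (IP-MS)
    experiments: SAINT specificity aggregation, bait normalization,
    replicate selection by coefficient of variation, differential
    interaction calling, and stable-isotope interaction stability ratios.
    Seeded synthetic generators emulate every input so the full pipeline
    is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rlang,
    tibble,
    dplyr,
    tidyr,
    readr,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
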