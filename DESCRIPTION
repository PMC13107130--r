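Package: structscore
Title: Adjudicating Alternative Gene Models with Protein Structure Scores
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores competing structural annotations (gene models) of the
    same locus using confidence output from AlphaFold-3-class protein
    structure predictors, Foldseek structure searches against the PDB, and
    InterProScan domain matches. Implements per-model metric extraction
    (pLDDT summaries and threshold counts, pTM, mean PAE, masked Foldseek
    scores, InterPro domain lengths), signed delta scoring between old and
    new annotation versions, MaxAbs-scaled combined sums with win/lose
    calls, and pairwise ROC/AUC ranking of curated versus pre-curation
    models. A synthetic data generator emits paired gene models with
    realistic annotation error modes (translated introns, truncations,
    terminal extensions, frameshifted tails) in the exact file formats the
    readers consume, so the full pipeline is testable without external
    downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
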