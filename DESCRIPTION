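Package: immunopepscore
Title: Immunopeptidome Quality Control and Decision-Tree Peptide Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing HLA class I immunopeptidomes from
    LC-MS/MS peptide identification tables. Reads PEAKS-style database-search
    and de novo exports, applies quality-control filters (de novo average
    local confidence, affinity-purification contaminant removal,
    sequence-level deduplication) and summaries (length and charge
    distributions, two-group ion-mobility geometry, CRAPome expected-protein
    fractions), interfaces with MHC class I binding (NetMHCpan-4.1 output)
    and immunogenicity (IEDB class I immunogenicity output) predictions, and
    ranks peptides with a three-stage Immunopeptidome Score decision tree
    (length 8-12 residues, strong binding to at least one allele, positive
    predicted immunogenicity). Includes deterministic stand-in predictors,
    funnel and cross-sample overlap reports, and a synthetic identification
    table generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
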