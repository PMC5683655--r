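Package: drmpeaks
Title: Consensus Binding, Differential Occupancy and Target Classification
    for the C. elegans DRM (DREAM) Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-subunit chromatin immunoprecipitation
    peak data for the C. elegans DRM (DREAM) transcriptional repressor
    complex. Builds high-confidence consensus binding sites from per-subunit,
    per-replicate peak calls by replicate-reproducibility filtering and
    subunit overlap voting; classifies differential occupancy between
    wild-type and pocket-protein-null genotypes from fragment count tables
    with a negative-binomial Wald test and Benjamini-Hochberg FDR control;
    annotates peaks to promoters (including bidirectional promoters),
    introns, termination sites and intergenic space; scans peak sequences
    for conserved CDE and CHR motifs with an IUPAC mismatch budget and
    tests enrichment (hypergeometric, chi-squared); classifies bound genes
    into repression target groups from differential-expression calls; and
    ships a seeded synthetic-data generator with a planted ground truth so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
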