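Package: tcrkit
Title: T-Cell Receptor Repertoire Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline, scriptable analysis of T-cell receptor beta-chain
    CDR3 repertoires. Reads clonotype tables in four dialects (V(D)J-caller
    TSV, plain CDR3 lists, AIRR Rearrangement TSV, generic CSV), applies
    IMGT-based quality control, and computes general repertoire features
    (Renyi diversity profiles, clonality as one minus the Pielou evenness,
    CDR3 length distributions, V/J gene usage, V-J pairing, clonal
    composition, sequence logos). Builds Hamming-proximity CDR3 similarity
    networks with random-walk community detection, extracts 3-mer motif
    count matrices with prevalence and Mann-Whitney disease-specificity
    filters and a diffusion-map embedding with out-of-sample projection,
    and annotates repertoires against reference CDR3 databases by fuzzy
    search with at most one mismatch. Includes seeded generators for
    synthetic repertoires, cohorts with motif spike-ins, and annotation
    references, plus a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    stats,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
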