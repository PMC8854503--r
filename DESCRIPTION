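Package: b2rscan
Title: Detection of Dual-Antibody B Cells in Single-Cell V(D)J Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting allelically and isotypically included
    (dual light chain) B cells in single-cell immunoglobulin V(D)J
    repertoires. Reads per-cell contig annotation tables in the AIRR
    Rearrangement and 10x Genomics dialects, assembles and classifies
    per-cell clonotypes (one heavy chain; IgM/D versus class-switched;
    single versus dual light chain; IGHV4-34 usage), and computes
    per-sample repertoire summaries and group-comparison statistics.
    Includes a synthetic-repertoire generator with a receptor-editing
    model of distal Jkappa skew, and a mechanistic simulator of serum
    VH4-34 (9G4) antibody decoration of B-cell surfaces that explains
    why flow cytometry can over-count kappa+lambda+ B cells relative to
    sequencing-based truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    withr,
    stats,
    tools,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
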