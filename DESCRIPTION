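Package: lollipopr
Title: Protein Lollipop Diagrams of Cohort Mutation Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Turns cohort mutation tables (gene, sample, protein change,
    mutation type) into publication-quality protein lollipop diagrams.
    Parses HGVS-style protein-change strings, aggregates per-residue and
    per-alteration sample recurrence, retrieves protein length and domain
    annotations from UniProt or from local cached records for offline use,
    highlights alterations at or above a user-chosen recurrence cutoff, and
    lays out stems, domain tracks and annotation labels with a deterministic
    collision-free label-placement algorithm. Figures are emitted as
    canonical SVG with PNG, PDF and JPEG conversions, alongside tabular
    exports of the plotted data and domain information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    curl,
    dplyr,
    generics,
    ggplot2,
    jpeg,
    jsonlite,
    purrr,
    readr,
    rlang,
    rsvg,
    stringr,
    tibble,
    tidyr,
    utils,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
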