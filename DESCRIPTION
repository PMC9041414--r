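Package: gaoscope
Title: Comparative Genomics Toolkit for Glycogen-Accumulating Organisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tidy tools for the comparative-genomics workflow used to
    characterise glycogen-accumulating organisms (GAOs) and related
    Alphaproteobacteria: pairwise percent nucleotide identity on aligned
    16S rRNA genes with shared-indel exclusion, group-wise identity
    distributions and threshold-based taxonomic rank placement,
    fragment-based average nucleotide identity (ANI) with a species-boundary
    call, KEGG-module completeness scoring with a four-level status scheme,
    annotation rescue and diagnostic-gene overrides, cumulative GC-skew
    replication origin/terminus prediction with dnaA proximity, fixed-window
    coverage binning, and gene presence/absence matrices. Ships seeded
    simulators for every input so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    dplyr,
    generics,
    ggplot2,
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
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
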