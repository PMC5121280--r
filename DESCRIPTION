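Package: famsynt
Title: Gene-Family Microsynteny, Duplication, Selection and Divergence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for comparative gene-family evolution
    on annotated genomes: PSSM-based identification of family members carrying
    paired QLQ and WRC domains, neighbor-joining phylogeny with Poisson-corrected
    distances, bootstrap support and subfamily assignment, exon-intron structure
    comparison, anchor-centered microsynteny detection with tandem versus
    large-scale duplication classification, Nei-Gojobori (1986) Ka/Ks estimation
    with sliding-window selection scans, and Gu-style type-I and type-II
    functional divergence between subfamilies. Includes a genome simulator that
    plants gene-family histories (duplications, subfamily rate shifts, selection
    regimes) with full ground truth, so every stage is benchmarked end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    GenomicRanges,
    rtracklayer,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
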