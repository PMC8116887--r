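Package: kmerscout
Title: Reference-Free Somatic Mutation Detection by Tumor-Normal K-mer
    Comparison at Desk Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate somatic mutations by comparing k-mer content
    of a tumor and a matched normal read set, without a reference genome or
    alignment. Reads are decomposed into k-mers grouped by their middle k-2
    bases (stems) and strand-canonicalized stems (roots); a joint
    normal/tumoral k-mer histogram is built with a bounded-memory external
    Sort-Reduce, served through an immutable chunked key-value store with a
    band-pass filter, a Bloom filter, a multi-level implicit index and a
    frequency-predicted in-memory cache; reads carrying sample-exclusive
    k-mers with an almost-matching witness in the other sample are clustered
    by shared roots and anchor-aligned to reconstruct candidate break-points.
    Includes a synthetic tumor/normal read simulator with ground-truth
    mutation manifests for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
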