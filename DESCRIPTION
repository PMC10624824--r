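Package: gapfillr
Title: Reference-Guided Gap Closing and Assembly Concordance Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating and improving draft genome assemblies with a
    higher-contiguity donor assembly. Implements reference-guided closing of
    N-run gaps under four explicit flank-alignment criteria (alignment length,
    mean identity, colinear order/orientation, N-free donor sequence),
    base-level concordance statistics in synteny blocks, synteny coverage,
    assembly quality values (QV), windowed repeat-ratio comparisons with an
    exact/approximate Mann-Whitney U engine, mate-pair physical coverage at
    assembly gaps, and a seeded synthetic-genome degradation simulator that
    emits machine-readable truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    withr,
    seqinr,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    vcfR,
    Rcpp,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    yaml
LinkingTo: Rcpp
Config/testthat/edition: 3
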