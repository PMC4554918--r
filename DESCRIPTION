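Package: slimsplice
Title: Short Linear Motifs, Splice-Donor Strength and Isoform Diversity in
    Co-Repressor Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how short linear motifs (SLiMs) and
    alternative splicing diversify multi-exon genes, modelled on the
    NCoR-family nuclear co-repressors. Scans proteins for degenerate
    motif patterns such as the CoRNR box, maps hits onto encoding exons,
    scores nine-base 5' splice-donor windows in bits with position weight
    matrix and maximum-entropy models, enumerates single-base substitutions
    that create cryptic GT donors and filters them by reading-frame
    compatibility, surveys donor-site conservation across orthologous
    sequences by pairwise alignment, and enumerates transcript isoforms
    over binary alternative-splicing events together with each isoform's
    motif complement. A seeded synthetic-locus generator provides gene
    models with planted ground truth so the whole pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
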