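Package: orenhance
Title: Prediction of Mammalian Odorant-Receptor Gene Enhancer Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A purely sequence-based framework for nominating candidate
    enhancers ("elements") of mammalian odorant-receptor and related
    chemoreceptor genes. Gene-annotation exports are assembled into grouped
    receptor lists (MOE, VNO, olfactome, TCR), partitioned into clusters,
    miniclusters and solitary genes under a sweep of intergenic cutoff
    distances, and compared against an optimal univariate k-means
    architecture selected by BIC. Evolutionarily conserved segments around
    the resulting loci are harvested, broadened and screened with
    position-specific weight matrices using exact dynamic-programming
    p-values under a zero-order background, Benjamini-Hochberg q-values and
    a two-round significance procedure; a variant restricts the screen to
    segments carrying a 13-bp core motif shared by the H and P elements.
    A seedable synthetic-fixture generator emulates annotation, genome,
    conservation tracks and planted motif instances so the whole pipeline
    is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
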