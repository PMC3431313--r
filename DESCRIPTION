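Package: h1blocks
Title: Windowed Poisson Enrichment Blocks for Linker Histone ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps broad blocks of linker-histone enrichment from ChIP-seq
    coverage summarized in fixed 100-bp windows. Implements a one-sided
    Poisson enrichment test of ChIP versus input per window, peak calling at
    a raw p-value cutoff, 5-kb block significance profiling with a shuffled
    control, peak-density classification of genic and distal intergenic
    target loci and target genes, gene-family cluster detection with exact
    binomial enrichment, family-by-sample enrichment z-score matrices with
    hierarchical ordering, binding-expression integration (binned expression
    curves, fold-change deregulation calls after knockdown), a
    permutation-based peak-set exclusivity test, and a synthetic-data
    generator that plants enrichment blocks over clustered gene families
    with coupled repression so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
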