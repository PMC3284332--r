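Package: meiorec
Title: Crossover and Gene-Conversion Analysis of Whole-Chromosome Meioses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for whole-chromosome analysis of meiotic recombination
    from dense marker haplotypes of hemizygous chromatids.  Simulates
    recombinant chromatids with known crossover and noncrossover
    gene-conversion truth under a Poisson double-strand-break model with
    geometric conversion-tract extensions, detects and classifies crossover
    and conversion events from per-progeny haplotype calls, and jointly
    estimates the gene-conversion initiation rate and tract-length
    parameter by maximum likelihood with profile confidence intervals and
    likelihood-ratio tests.  Also provides Monte-Carlo tests of crossover
    clustering and exon avoidance, and motif statistics for crossover
    intervals: word counting with composition-based expectations, position
    weight matrix scanning with exact p-values, flank-enrichment tests
    with multiple-testing correction, and metamotif clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    rtracklayer,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
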