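Package: lncflower
Title: Long Noncoding RNA Discovery and Flowering-Regulator Inference from
    Short-Day and Night-Break RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the inference chain from assembled transcripts and
    RNA-seq counts to antagonistic (positive versus negative flowering)
    long noncoding RNA (lncRNA) regulators under a short-day / night-break
    photoperiod design. Provides lncRNA identification with positional
    classification (lincRNA, intronic, sense, antisense), FPKM expression
    profiling with per-condition expressed-set Venn partitions, a
    negative-binomial Wald test for differential expression with
    Benjamini-Hochberg correction, cis-window and Pearson-correlation trans
    target prediction, bipartite regulatory network construction with
    common-target intersection, hypergeometric gene-set enrichment, and a
    negative-binomial study simulator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
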