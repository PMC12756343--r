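Package: syntolog
Title: Synteny-Aware One-to-One Ortholog Inference for Annotated Genome Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls high-precision one-to-one orthologs between two annotated
    eukaryotic genomes by combining three lines of evidence: protein similarity
    normalized with a modified Jaccard index, nucleotide-level conservation of
    concatenated exonic sequence extended by flanking exonic sequence from
    adjacent genes, and microsynteny scored over a 20-locus neighborhood.
    Candidate homolog pairs are evaluated against all competing pairs sharing
    either gene under a dual rule set (with and without microsynteny support),
    orthologs to a primary anchor genome can be inferred transitively through a
    clade anchor, accepted pairs are consolidated into anchor-keyed ortholog
    sets, and informative gene symbols are propagated from the anchor to set
    members. A deterministic genome-pair simulator with planted ortholog truth
    supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    methods,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
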