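Package: coppermine
Title: Genomic-Context Discovery of Small Periplasmic Copper Chaperones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based and iterative profile-HMM discovery of small
    CutF-like copper chaperone proteins from prokaryotic genomic context.
    Provides gene-neighborhood extraction around multicopper-oxidase anchor
    genes, a five-rule candidate filter (size, Pfam-domain absence, signal
    peptide, central CXXXC-type cysteine motif, C-terminal PP motif),
    progressive multiple alignment with motif-column curation, profile hidden
    Markov models with Gumbel-calibrated E-values and jackhmmer-style
    iterative family expansion, sequence-similarity-network clustering of
    multicopper oxidases, genomic co-occurrence statistics, neighbor-joining
    phylogenies with bootstrap-support pruning, multicopper-oxidase activity
    assay arithmetic, and a synthetic proteome generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
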