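Package: pantascan
Title: Gene-Neighborhood Prediction of Panacea-Associated Toxin-Antitoxin Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics pipeline for discovering putative Type II
    toxin-antitoxin (TA) loci anchored on a seed antitoxin domain such as
    Panacea (DUF4065). Detects seed-domain proteins with a position-specific
    scoring profile (or injected HMMER3 domain tables), clusters the proteins
    flanking every seed gene into homologous families across genomes, calls
    conserved two- or three-gene operonic loci (gap at most 100 nt, conserved
    in at least two species, no conserved architectures longer than three
    genes), removes spurious partner families with a reciprocal genomic
    context test, annotates candidates (N-terminal helix-turn-helix
    re-modelling, discovery of novel conserved extensions, hydropathy-based
    transmembrane segments, alignment conservation profiles), and reports
    corpus-level summary statistics. Includes a seeded synthetic pangenome
    simulator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    igraph,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    withr
Config/testthat/edition: 3
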