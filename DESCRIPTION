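Package: mirseed
Title: Small-RNA miRNA Identification and Characterization Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for microRNA discovery from small-RNA
    sequencing libraries of the green microalga Coccomyxa subellipsoidea
    C-169 and similar desk-scale genomes. Covers adapter trimming and read
    collapsing, exact and one-mismatch mapping of unique reads to a genome
    and to a reference mature-miRNA catalog, hairpin precursor folding with
    a bundled deterministic secondary-structure backend, an eleven-criterion
    structural filter for novel miRNA discovery, miRNA family statistics,
    complementarity penalty-scored target prediction, reads-per-million
    expression quantification with qRT-PCR delta-delta-Ct arithmetic, and
    hypergeometric term enrichment with rich factors. A synthetic-data
    module generates genomes with planted hairpin precursors, two-condition
    read libraries, transcriptomes with planted target sites and matched
    qPCR measurements, with full ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
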