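Package: dmtrnaseq
Title: Nucleotide-Resolution Analysis of Mitochondrial tRNA Modifications
    from DM-tRNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for demethylase tRNA sequencing
    (DM-tRNA-seq) of the mitochondrial tRNA pool. Computes per-position
    mutation and reverse-transcriptase stop fractions and their sum, the
    Modification Index (MI), from ungapped best-stratum alignments of
    3'-anchored reads; calls demethylase-sensitive methyl sites from
    matched treated/untreated libraries; estimates sub-stoichiometric
    modified fractions near the tRNA 3' end; classifies 3' CCA status and
    oligoadenylation; and quantifies tRNA abundance and mitochondrial DNA
    heteroplasmy. Ships a synthetic-read generator with full per-read
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
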