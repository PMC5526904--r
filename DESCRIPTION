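Package: OhnologEvo
Title: Molecular Evolution of Whole-Genome-Duplication Paralog Families
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for tracing the evolutionary history of gene families
    retained from whole-genome duplication (ohnologs): homolog screening over
    HMMER/BLAST tabular output (domain-hit filtering, redundancy clustering,
    reverse-best-hit orthology), outgroup-anchored synteny-block detection,
    Nei-Gojobori (1986) pairwise dN/dS with clade and domain summaries, a
    Goldman-Yang (1994) codon-substitution likelihood engine with branch,
    clade (model C / M2a_rel) and branch-site models plus likelihood-ratio
    tests, and Gu-style type-I functional divergence with iterative
    posterior-cutoff site selection. Ships synthetic-data generators with
    machine-readable ground truth so every stage can be exercised and
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
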