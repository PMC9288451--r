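Package: fibrocouple
Title: Transcriptome-Phenotype Coupling for Longitudinal Lung-Fibrosis Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples longitudinal bulk RNA-seq (mRNA and miRNA) expression
    changes to lung-function decline in two mouse models of pulmonary
    fibrosis (bleomycin injury and AAV-mediated TGFb1 overexpression).
    Provides per-model, per-day differential expression on log-CPM;
    correlation of log2 fold-change trajectories with lung compliance;
    mouse-human miRNA seed-region conservation scoring by global
    alignment; anticorrelation-based miRNA-mRNA target pairing
    intersected with sequence-based predictions; assembly of an
    annotated regulatory network; and a staged miRNA hit-selection
    cascade. Includes a negative-binomial study simulator with planted
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
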