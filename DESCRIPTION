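Package: relapsevo
Title: Clonal Evolution and Driver Analyses for Paired Primary-Relapse
    Myeloma Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for whole-genome analyses of paired
    primary and relapsed IGH-translocated multiple myeloma tumours:
    Poisson-binomial recurrence and positional-clustering tests for
    noncoding driver discovery in promoters and cis-regulatory elements,
    cancer-cell-fraction chronology of driver events with discrete
    clonality levels and basic-bootstrap confidence intervals, paired
    permutation tests for chromosome-arm copy-number dynamics,
    Dirichlet-process clustering of mutations in two-dimensional CCF
    space with rule-based classification of clonal evolution patterns,
    mutational-signature extraction, refitting and relapse dynamics, and
    rule-based kataegis and chromothripsis detection. A synthetic cohort
    generator plants every modelled effect with a machine-readable ground
    truth so that the full pipeline is testable without access to
    controlled sequencing data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
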