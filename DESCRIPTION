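Package: clonesim
Title: Simulation and Analysis of Clonal Dynamics in Barcoded Cell Populations
Version: 0.1.0
Authors@R:
    person("Maarten", "de Wit", email = "mdewit@example.org", role = c("aut", "cre"))
Description: Tools to study how clonal dominance arises in iterated
    growth-and-passage experiments on lentivirally barcoded tumour cell lines.
    Provides clone-level growth engines (deterministic exponential growth, a
    tau-leaping stochastic birth process, and an age-structured cancer stem
    cell model), an agent-based model of individual cells with heritable,
    mutating division rates, summary statistics of clonal dominance (clone
    loss, Gini coefficient, major-clone counts, dominance curves), a
    likelihood-grid fit of the agent-based model to reference trajectories,
    and synthetic barcode data generators (clone-size distributions, FASTQ
    reads, reference libraries, spurious-read contamination) so the complete
    pipeline can be exercised without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
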