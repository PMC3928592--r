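Package: lnblood
Title: Hybrid Lymph Node and Blood Simulator of T Cell Priming, Differentiation and Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-compartment immune simulator coupling a spatially explicit
    agent-based model of a lymph node paracortex (T cell recruitment through
    high endothelial venules, motility on a truncated-cone lattice, cognate
    binding to antigen-bearing and licensed dendritic cells, signal-strength
    driven activation checkpoints, clonal expansion, effector/central-memory/
    effector-memory differentiation, and efferent-lymphatic egress) to an
    ordinary-differential-equation model of the well-mixed blood compartment
    (thymic output with annual decline, subset-specific turnover, recruitment
    to sites of infection, and effector-memory to central-memory conversion).
    Includes experiment drivers for primary and recall infections, dendritic
    cell ablation, DC-number/pMHC sweeps and single-precursor lineage tracing,
    plus Latin hypercube sampling and partial rank correlation coefficient
    sensitivity analysis, and a command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
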