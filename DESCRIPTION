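Package: fluxpath
Title: Constraint-Based Flux Sampling, Differential Flux Analysis and
    Knockout Candidate Ranking for Central-Carbon Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing metabolic flux states of
    constraint-based models and for the omics quality-control rules used
    alongside them. Reads and writes a documented JSON model dialect
    (with optional SBML level-3 FBC import), performs flux balance
    analysis and flux variability analysis, applies measured-rate and
    13C-MFA confidence-interval constraints with a greedy elastic repair
    of conflicting intervals, samples the steady-state flux polytope
    with an artificial-centering hit-and-run chain (with a mixed-fraction
    convergence diagnostic), tests for differential flux, metabolite
    utilization and subsystem utilization between conditions with
    permutation p-values and geometric fold-changes, ranks reaction
    knockout candidates by sampled flux, measurable neighbors and gene
    count, and provides metabolomics QC/imputation/glog-normalization,
    growth-rate and fitness-trajectory fitting, mutation-table filters
    and coverage-based duplication calling. A synthetic central-carbon
    network generator with known ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
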