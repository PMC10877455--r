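Package: depstrat
Title: Criteria-Stratified Case-Control Analysis of Brain Structure and
    Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage analysis of how the operational definition of
    lifetime depression shapes case-control neuroimaging findings.
    Computes voxel-wise resting-state measures (fractional amplitude of
    low-frequency fluctuations, local and global correlation) and relative
    gray-matter volume, stratifies cases by the exact number of diagnostic
    criteria met, runs covariate-adjusted voxel-wise Welch tests with
    permutation-based cluster-level family-wise error control, quantifies
    every criteria constellation against a single control pool with
    Cohen's d, and attributes observed effects to individual criteria via
    a difference-in-effect-size statistic. Includes a synthetic-cohort
    generator with planted, criterion-linked effects so the full pipeline
    is testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
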