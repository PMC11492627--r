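Package: mrtriangle
Title: Correlation-Aware Two-Sample Mendelian Randomisation with
    Directional Triangulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample Mendelian randomisation from GWAS summary statistics
    using the generalised least squares implementation of the
    inverse-variance-weighted estimator and the Egger correction for
    correlated (LD-clumped) instruments, with heterogeneity-based model
    selection, leverage and outlier pruning, cis-window instrument selection
    for protein exposures, and allele harmonisation. Downstream, directionally
    concordant protein-metabolite-outcome triangles are assembled for
    drug-target prioritisation, annotated with tissue expression and
    druggability, and assessed with Wald proportion-based enrichment and
    replication rules. Includes a summary-statistic simulator with known
    causal structure so the full workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
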