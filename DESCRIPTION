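Package: tcsp
Title: T Cell Subtype Profiling by Signature-Based Deconvolution of Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("TCSP", "Maintainers", email = "maintainers@tcsp.example.org",
           role = c("aut", "cre"))
Description: Builds five T-cell subtype expression models (naive, activated,
    exhausted, effector memory, central memory) from labeled reference RNA-seq
    profiles via fold-difference ranking, variability and abundance gates, and
    tumor background filtering; estimates per-sample subtype mRNA fractions
    from bulk count tables by solving the linear mixture B = S * F with
    epsilon-insensitive linear support-vector regression; generates seeded
    synthetic references, tumor background panels and count-level titrations
    with known ground-truth fractions; and evaluates multianalyte response
    biomarkers with bootstrap out-of-bag cross-validation, ROC/AUC,
    Kaplan-Meier/log-rank and one-sided Mann-Whitney statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    survival,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
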