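Package: dualTrace
Title: Dual-Precursor Stable-Isotope Labeling Analysis of LC-MS Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of dual-precursor ring-13C6 stable-isotope labeling
    experiments on untargeted LC-MS feature tables. Detects co-eluting
    12C/13C isotopologue peak pairs validated by enrichment in isotope-fed
    samples, quantifies the labeled fraction of each metabolite pool and
    converts paired labeled fractions into mol percent precursor-of-origin
    values, classifies features into precursor-bias bins with a Welch t-test
    filter, summarises labeled ion-count shares, and retrospectively
    annotates unlabeled feature tables (e.g. mutant genotypes) against the
    resulting precursor-origin library with differential-abundance testing.
    Includes a synthetic-data generator that emulates a multi-tissue,
    two-precursor, two-isotope replicated feeding design with planted
    ground truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
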