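Package: dmsdiff
Title: Differential DMS Reactivity Analysis for Structure-seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing dimethyl-sulphate (DMS) chemical probing
    experiments of the Structure-seq2 type, from reverse-transcriptase stop
    counts to normalized per-nucleotide reactivities and differential
    structure statistics. Implements per-transcript coverage and 5' end
    coverage quality filters, shared-scale reactivity normalization,
    replicate averaging and delta reactivity, regional averages and Gini
    coefficients, binned meta-profiles, sliding-window detection of
    localized structure remodeling in 5'UTRs, GGC/GCC repeat motif
    reactivity normalization, polysome-profiling translational efficiency,
    and a Bayesian difference-of-differences classifier of helicase
    dependency. A seeded synthetic-data generator emulates the statistical
    structure of such experiments so the full pipeline can be exercised and
    validated against known ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
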