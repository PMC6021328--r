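Package: gapstrat
Title: Gene Amplification Profile Stratification of Glioblastoma
Version: 0.1.0
Authors@R: person("GAP", "Maintainers", email = "maintainers@gapstrat.example.org",
    role = c("aut", "cre"))
Description: Calls high-level somatic amplicons (more than seven DNA copies,
    above 4.8 arbitrary copy-number units) from paired tumor/normal SNP-array
    copy-number tracks, aggregates them to chromosome arms, cytobands and
    genes, assigns each glioblastoma to one of five gene-amplification-profile
    (GAP) classes and one of two prognostic risk groups, and quantifies the
    prognostic impact with Kaplan-Meier curves, log-rank tests and forward
    stepwise Cox regression. Ships a synthetic paired-cohort simulator and a
    transcribed 80-patient reference cohort so the whole pipeline runs without
    any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
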