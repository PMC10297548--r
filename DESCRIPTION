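Package: aeburden
Title: Longitudinal Burden-of-Therapy Scoring for Adverse Events in
    Two-Arm Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the longitudinal burden of treatment-emergent
    adverse events (TEAEs) in two-arm clinical trials. For every patient
    and study week a grade-weighted burden score is computed as the sum
    over distinct adverse-event terms of the highest CTCAE grade active
    that week, optionally multiplied by per-term clinical-relevance
    weights. Weekly arm totals are normalized by the number of subjects
    still at risk, accumulated into a per-arm area under the curve (AUC),
    and compared between arms with a label-permutation test. Includes
    readers for delimited AE listing and disposition tables with
    configurable column mapping, a mirrored severity-stacked bar chart of
    the weekly burden, a configurable two-arm trial simulator for method
    evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
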