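Package: pharmsig
Title: Multi-Source Pharmacovigilance Signal Detection and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects adverse-drug-event (ADE) signals for a (drug, indication)
    pair from two complementary sources: reporting odds ratios (ROR) computed
    on 2x2 contingency tables of spontaneous reports, and odds ratios from an
    unconditional case-crossover analysis of longitudinal patient event
    streams, where each patient's pre-exposure period serves as their own
    control. Signal sets are mapped onto drug side-effect knowledge bases
    (SIDER- and ADReCS-style dialects) either exactly by UMLS concept
    identifier or flexibly through downward expansion over a five-level
    MedDRA-like hierarchy, and scored with precision, recall and F1. Signals
    absent from the knowledge bases are ranked as novel-ADE hypotheses with
    Bonferroni-corrected p-values. A deterministic synthetic-data module
    generates hierarchies, knowledge bases, spontaneous-report tables and
    patient timelines with planted effects of known magnitude, so the whole
    pipeline is testable end to end without access to licensed terminologies
    or protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
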