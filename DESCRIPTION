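Package: formulanet
Title: Network-Pharmacology Screening and Formula-Reduction Analysis for
    Multi-Herb Medicines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for systems-pharmacology analysis of multi-component
    traditional medicines: hypergeometric herb-disease co-occurrence testing
    on literature counts, ADME candidate screening by oral bioavailability
    and Tanimoto drug-likeness thresholds with literature-based rescue lists,
    dual-model (random forest + support vector machine) target-score consensus
    filtering, bipartite compound-target network statistics
    (degrees, shared/specific target partitions, overlap percentages),
    compound-target-pathway mapping, and an alternative-removing comparison
    that decides whether a component set can be deleted from a formula
    without losing disease-relevant target coverage. Ships transcriptions of
    the published compound tables of the modified Yimusake formula and its
    three animal drugs, plus a synthetic-data generator with planted ground
    truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
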