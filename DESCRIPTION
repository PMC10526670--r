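Package: cernascreen
Title: Screening ceRNA Regulatory Axes from Pull-Down Enrichment to
    Prognostic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for nominating competing endogenous RNA
    (ceRNA) regulatory axes anchored on a 3'-UTR bait. Implements
    tags-per-million normalization and enrichment ranking of RNA pull-down
    miRNA libraries, RPKM quantification with a fold-change/p-value
    differential expression filter, canonical seed-match miRNA target
    prediction (8mer, 7mer-m8, 7mer-A1, 6mer), from-scratch survival
    statistics (Kaplan-Meier, log-rank, Cox proportional hazards with Efron
    ties, Spearman rank correlation), in situ hybridization composite
    scoring with Youden-index cutoff selection, and a multi-stage
    intersection cascade that emits a core-anchored ceRNA network with a
    per-stage report. A synthetic-data module generates every pipeline
    input with planted ground truth so the whole cascade is testable end to
    end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
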