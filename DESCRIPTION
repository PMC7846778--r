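Package: cgimeth
Title: CpG-Island Methylation Gain, Re-Methylation Kinetics and Spike-In
    ChIP Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies CpG-island (CGI) methylation from per-CpG bisulfite
    read counts and calls differential methylation gain with exact tests and
    false-discovery-rate control; analyses re-methylation kinetics after
    5-aza-2'-deoxycytidine treatment by comparing an outgrowth-only
    random-intercept mixed model against a heterogeneous-rate random-slope
    model and estimating per-CGI recovery rates; performs input-corrected
    spike-in (ChIP-Rx) normalisation of ChIP-seq counts with decile
    association and histone-mark linear modelling; and runs CGI-mapped
    ontology-term enrichment with Wang semantic-similarity collapsing.
    Includes generators for synthetic bisulfite counts, methylation
    time courses, spike-in ChIP experiments and ontologies with known
    ground truth, and a deterministic end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    lme4,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
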