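Package: rhizovirome
Title: Viral Community Analysis for Rhizosphere Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream community analysis of soil viral populations (vOTUs)
    recovered from bulk metagenomes of plant root-zone compartments. Calls
    vOTU presence from breadth of mapping coverage, computes transcripts per
    million (TPM) relative abundance, richness, rarefaction and
    Bray-Curtis/NMDS/PERMANOVA ordination statistics, classifies multi-sample
    vOTUs into phenotype and compartment sharing classes and tests them
    against a richness-conserving randomization null model, applies
    annotation-level filters (HMM hit thresholds, positional auxiliary
    metabolic gene rule, host-order biogeochemical tagging), and ships a
    synthetic-data generator emulating a 2-phenotype x 3-compartment x
    4-replicate study design so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    Biostrings
Config/testthat/edition: 3
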