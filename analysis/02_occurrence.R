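#!/usr/bin/env Rscript
# Stage 2 — vOTU occurrence and abundance.
#
# Calls presence per (vOTU, sample) at >= 75% breadth of coverage and
# computes TPM relative abundance, then verifies the calls against the
# simulator's ground truth (they must agree exactly: the generator keeps
# present and absent breadth supports on opposite sides of the threshold).

suppressPackageStartupMessages(library(rhizovirome))
out <- "results/analysis"

coverage <- read_coverage_csv(file.path(out, "coverage.csv"))
truth <- read_occurrence_csv(file.path(out, "ground_truth.csv"))

occ <- call_presence(coverage, breadth_threshold = 0.75)
tpm <- compute_tpm(coverage, mask_absent = FALSE)
write_occurrence_csv(occ, file.path(out, "occurrence.csv"))
write_abundance_csv(tpm, file.path(out, "abundance_tpm.csv"))

agree <- identical(occ[rownames(truth), colnames(truth)], truth)
cat(sprintf("presence calls: %d of %d (vOTU, sample) pairs present; ground truth recovered: %s\n",
            sum(occ), length(occ), agree))
stopifnot(agree)
cat(sprintf("TPM columns sum to 1e6 (max abs deviation %.2e)\n",
            max(abs(colSums(tpm) - 1e6))))
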