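#!/usr/bin/env Rscript
# Stage 3 — richness, rarefaction and beta-diversity.
#
# Per-sample richness with pairwise Mann-Whitney comparisons between
# phenotype x compartment cells (exact test at n = 4 per group),
# a 100-permutation sample-accumulation curve, and Bray-Curtis -> NMDS +
# PERMANOVA on the TPM abundances.

suppressPackageStartupMessages(library(rhizovirome))
out <- "results/analysis"
seed <- 42L

design <- read.csv(file.path(out, "design.csv"), stringsAsFactors = FALSE)
occ <- read_occurrence_csv(file.path(out, "occurrence.csv"))
tpm <- read_abundance_csv(file.path(out, "abundance_tpm.csv"))

rich <- richness(occ, design)
write.csv(rich, file.path(out, "richness.csv"), row.names = FALSE)
cat("mean richness by cell:\n")
print(aggregate(richness ~ phenotype + compartment, rich, mean))

tests <- pairwise_richness_tests(rich)
write.csv(tests, file.path(out, "richness_tests.csv"), row.names = FALSE)
sig <- tests[tests$p_value < 0.05, ]
cat(sprintf("%d of %d pairwise richness comparisons significant at 0.05\n",
            nrow(sig), nrow(tests)))

rar <- rarefaction(occ, n_permutations = 100, seed = seed)
write.csv(data.frame(k = rar$k, mean_richness = rar$mean_richness),
          file.path(out, "rarefaction.csv"), row.names = FALSE)
total <- sum(rowSums(occ) > 0)
cat(sprintf("accumulation curve: %.0f vOTUs at k=1 rising to %d at k=%d (saturating: %s)\n",
            rar$mean_richness[1], total, ncol(occ),
            ifelse(diff(tail(rar$mean_richness, 2)) < 1, "yes", "no")))

bc <- bray_curtis(tpm)
write_dissimilarity_csv(bc, file.path(out, "bray_curtis.csv"))
ord <- nmds(bc, k = 2, n_restarts = 20, seed = seed)
write.csv(data.frame(sample_id = rownames(ord$points), ord$points,
                     stress = ord$stress),
          file.path(out, "nmds.csv"), row.names = FALSE)
cat(sprintf("NMDS stress: %.3f (%d restarts)\n", ord$stress, ord$n_restarts))

i <- match(colnames(occ), design$sample_id)
pm_ph <- permanova(bc, design$phenotype[i], 999, seed = seed)
pm_cp <- permanova(bc, design$compartment[i], 999, seed = seed)
pm <- data.frame(term = c("phenotype", "compartment"),
                 F = c(pm_ph$F, pm_cp$F), R2 = c(pm_ph$R2, pm_cp$R2),
                 p_value = c(pm_ph$p_value, pm_cp$p_value))
write.csv(pm, file.path(out, "permanova.csv"), row.names = FALSE)
cat("PERMANOVA:\n"); print(pm, row.names = FALSE)
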