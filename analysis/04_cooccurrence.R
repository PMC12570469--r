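#!/usr/bin/env Rscript
# Stage 4 — sharing classes and the richness-conserving null model.
#
# Restricts to vOTUs found in >= 2 samples, classifies each by the set of
# phenotypes and compartments it spans, and compares the observed class
# counts to a null that redraws each sample's vOTU identities uniformly
# while conserving its richness (1,000 replicates, chi-squared test).

suppressPackageStartupMessages(library(rhizovirome))
out <- "results/analysis"
seed <- 42L

design <- read.csv(file.path(out, "design.csv"), stringsAsFactors = FALSE)
occ <- read_occurrence_csv(file.path(out, "occurrence.csv"))

multi <- multi_sample_filter(occ)
cat(sprintf("%d of %d vOTUs occur in >= 2 samples (%d singletons, %.0f%%)\n",
            nrow(multi), nrow(occ), nrow(occ) - nrow(multi),
            100 * (nrow(occ) - nrow(multi)) / nrow(occ)))

tabs <- list(); tests <- list()
for (cls in c("phenotype", "compartment")) {
  nm <- null_model(occ, design, cls, n_replicates = 1000,
                   mode = "per_sample", seed = seed)
  tab <- sharing_class_table(nm)
  tabs[[cls]] <- cbind(classification = cls, tab)
  tests[[cls]] <- data.frame(classification = cls, chi2 = nm$chi2,
                             df = nm$df, p_value = nm$p_value)
  cat(sprintf("\n%s sharing (chi2 = %.1f, df = %d, p = %.3g):\n",
              cls, nm$chi2, nm$df, nm$p_value))
  print(tab, row.names = FALSE, digits = 3)
}
write.csv(do.call(rbind, tabs), file.path(out, "sharing_classes.csv"),
          row.names = FALSE)
write.csv(do.call(rbind, tests), file.path(out, "null_model_tests.csv"),
          row.names = FALSE)

both <- tabs$phenotype[tabs$phenotype$class == "both-phenotypes", ]
cat(sprintf("\ncross-phenotype sharing: observed %d vs %.0f expected -> %s than chance\n",
            both$observed, both$expected,
            ifelse(both$observed < both$expected, "less", "more")))
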