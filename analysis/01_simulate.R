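#!/usr/bin/env Rscript
# Stage 1 — simulate study inputs.
#
# Generates the 24-sample crossed design (2 phenotypes x 3 compartments x
# 4 replicates) and a synthetic virome at study scale: 769 vOTUs with
# log-uniform contig lengths, strong phenotype fidelity, and a
# compartment-proximity gradient (no exclusive bulk+root sharing). Also
# simulates the annotation-side inputs: per-contig gene tables and an
# order-level host-prediction table. Everything downstream reads the CSVs
# written here.

suppressPackageStartupMessages(library(rhizovirome))

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 42L

design <- generate_design(4)
write.csv(design, file.path(out, "design.csv"), row.names = FALSE)

params <- sim_params(seed = seed)
sim <- generate_coverage(design, params)
write_coverage_csv(sim$coverage, file.path(out, "coverage.csv"))
write_occurrence_csv(sim$occupancy, file.path(out, "ground_truth.csv"))

genes <- generate_gene_tables(n_contigs = 200, genes_per_contig = c(5, 40),
                              p_viral = 0.6, p_metabolic = 0.05, seed = seed)
write.csv(genes, file.path(out, "gene_table.csv"), row.names = FALSE)

orders <- data.frame(order = sprintf("order_%02d", 1:22),
                     phylum = sprintf("phylum_%02d", rep_len(1:14, 22)))
hosts <- generate_host_table(rownames(sim$occupancy), orders,
                             p_assigned = 0.083, seed = seed)
write.csv(hosts, file.path(out, "host_table.csv"), row.names = FALSE)
functions <- data.frame(
  order = orders$order[1:9],
  func = rep(c("sulfur-oxidizing", "sulfate-reducing", "iron-oxidizing"), 3))
write.csv(functions, file.path(out, "function_table.csv"), row.names = FALSE)

occ_rate <- mean(colSums(sim$occupancy))
cat(sprintf(
  "simulated %d vOTUs x %d samples (mean per-sample richness %.0f)\n",
  nrow(sim$occupancy), ncol(sim$occupancy), occ_rate))
cat(sprintf("gene table: %d genes on %d contigs; hosts predicted for %d vOTUs (%.1f%%)\n",
            nrow(genes), length(unique(genes$contig_id)), nrow(hosts),
            100 * nrow(hosts) / nrow(sim$occupancy)))
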