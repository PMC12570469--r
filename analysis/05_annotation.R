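#!/usr/bin/env Rscript
# Stage 5 — annotation filters and host-function tagging.
#
# Applies the HMM hit filter (bit score > 30, e-value <= 0.01), the
# positional AMG rule (interior metabolic genes flanked by viral genes on
# both sides), and joins host predictions to order-level biogeochemical
# functions, summarized per phenotype x compartment cell.

suppressPackageStartupMessages(library(rhizovirome))
out <- "results/analysis"

genes <- read.csv(file.path(out, "gene_table.csv"), stringsAsFactors = FALSE)
hosts <- read.csv(file.path(out, "host_table.csv"), stringsAsFactors = FALSE)
functions <- read.csv(file.path(out, "function_table.csv"),
                      stringsAsFactors = FALSE)
design <- read.csv(file.path(out, "design.csv"), stringsAsFactors = FALSE)
occ <- read_occurrence_csv(file.path(out, "occurrence.csv"))

hits <- filter_hits(genes, min_bitscore = 30, max_evalue = 0.01)
cat(sprintf("hit filter kept %d of %d annotations\n", nrow(hits), nrow(genes)))
write.csv(hits, file.path(out, "filtered_hits.csv"), row.names = FALSE)

amg <- suppressMessages(flag_amg(genes, flank = 1))
write.csv(amg, file.path(out, "amg_candidates.csv"), row.names = FALSE)
cat(sprintf("AMG positional filter: %d candidate(s) among %d metabolic genes\n",
            nrow(amg), sum(genes$annotation_class == "metabolic")))

tg <- tag_host_functions(hosts, functions)
write.csv(tg$tags, file.path(out, "host_function_tags.csv"), row.names = FALSE)
s <- tg$summary
cat(sprintf("hosts: %d vOTUs, %d phyla, %d orders (%d with biogeochemical roles); %.0f%% of hosted vOTUs target functional taxa\n",
            s$n_votus, s$n_phyla, s$n_orders, s$n_functional_orders,
            100 * s$fraction_votus_functional))

sm <- summarize_host_predictions(hosts, occ, design)
write.csv(sm$cells, file.path(out, "host_summary_cells.csv"), row.names = FALSE)
write.csv(sm$phyla, file.path(out, "host_summary_phyla.csv"), row.names = FALSE)
cat("host predictions per phenotype x compartment cell:\n")
print(sm$cells, row.names = FALSE, digits = 3)
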