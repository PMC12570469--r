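#' Pipeline configuration
#'
#' Collects every threshold, permutation count and mode switch of the
#' analysis, with defaults matching the analysis conventions used
#' throughout the package (presence breadth 0.75, 5 kb minimum contig,
#' 95% ANI / 80% coverage dereplication, bit score 30 / e-value 0.01 hit
#' filter, 100 rarefaction permutations, 1000 null-model replicates, 999
#' PERMANOVA permutations). Every value is validated against its domain.
#'
#' @param breadth_threshold presence threshold on covered fraction, in
#'   (0, 1\].
#' @param min_length minimum contig length (bp).
#' @param ani_threshold,cov_threshold dereplication thresholds in \[0, 1\].
#' @param min_bitscore,max_evalue annotation hit filter.
#' @param n_rarefaction,n_null,n_permanova permutation counts (>= 1).
#' @param mask_absent TPM masking switch (see [compute_tpm()]).
#' @param null_mode "per_sample" or "per_cell" (see [null_model()]).
#' @param flank AMG flank width (>= 1).
#' @param seed integer seed for all randomized stages.
#' @param sim optional [sim_params()] for the synthetic input stage.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(breadth_threshold = 0.75, min_length = 5000,
                            ani_threshold = 0.95, cov_threshold = 0.80,
                            min_bitscore = 30, max_evalue = 0.01,
                            n_rarefaction = 100, n_null = 1000,
                            n_permanova = 999, mask_absent = FALSE,
                            null_mode = "per_sample", flank = 1,
                            seed = 1L, sim = NULL) {
  in_unit <- function(x, what, lo = 0, hi = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= lo || x > hi) {
      stop(what, " must lie in (", lo, ", ", hi, "]")
    }
  }
  in_unit(breadth_threshold, "breadth_threshold")
  in_unit(ani_threshold, "ani_threshold")
  in_unit(cov_threshold, "cov_threshold")
  stopifnot(min_length > 0, min_bitscore >= 0, max_evalue > 0,
            n_rarefaction >= 1, n_null >= 1, n_permanova >= 1, flank >= 1)
  if (!null_mode %in% c("per_sample", "per_cell")) {
    stop("null_mode must be 'per_sample' or 'per_cell'")
  }
  structure(list(
    breadth_threshold = breadth_threshold, min_length = min_length,
    ani_threshold = ani_threshold, cov_threshold = cov_threshold,
    min_bitscore = min_bitscore, max_evalue = max_evalue,
    n_rarefaction = as.integer(n_rarefaction), n_null = as.integer(n_null),
    n_permanova = as.integer(n_permanova), mask_absent = mask_absent,
    null_mode = null_mode, flank = as.integer(flank), seed = as.integer(seed),
    sim = if (is.null(sim)) sim_params(seed = seed) else sim
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes occurrence -> diversity -> co-occurrence -> annotation on the
#' given inputs, writing tidy CSV outputs plus a JSON run manifest under
#' `out_dir`. Inputs default to synthetic data drawn from `config$sim`, so
#' a bare `run_pipeline(pipeline_config(), out_dir)` is a complete smoke
#' run. The annotation stage is skipped when no gene/host tables are
#' supplied or simulated.
#'
#' @param config [pipeline_config()] object.
#' @param out_dir output directory (created if needed).
#' @param coverage optional coverage summary data.frame; simulated when
#'   NULL.
#' @param design optional sample table; defaults to [generate_design()].
#' @param genes,hosts,functions optional annotation inputs; simulated when
#'   NULL and `simulate_annotation` is TRUE.
#' @param simulate_annotation simulate gene/host tables when not supplied.
#' @return invisible list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir, coverage = NULL, design = NULL,
                         genes = NULL, hosts = NULL, functions = NULL,
                         simulate_annotation = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(design)) design <- generate_design(4)
  .check_design(design)

  written <- character(0)
  emit <- function(obj, name, writer = utils::write.csv) {
    path <- file.path(out_dir, name)
    if (identical(writer, utils::write.csv)) {
      utils::write.csv(obj, path, row.names = FALSE, quote = FALSE)
    } else {
      writer(obj, path)
    }
    written <<- c(written, name)
  }

  truth <- NULL
  if (is.null(coverage)) {
    sim <- generate_coverage(design, config$sim)
    coverage <- sim$coverage
    truth <- sim$occupancy
    emit(coverage, "coverage.csv")
    emit(data.frame(votu_id = rep(rownames(truth), ncol(truth)),
                    sample_id = rep(colnames(truth), each = nrow(truth)),
                    present = as.integer(truth)),
         "ground_truth.csv")
  }
  message("occurrence stage: ", length(unique(coverage$votu_id)), " vOTUs x ",
          length(unique(coverage$sample_id)), " samples")

  occ <- call_presence(coverage, config$breadth_threshold)
  tpm <- compute_tpm(coverage, config$mask_absent, config$breadth_threshold)
  emit(occ, "occurrence.csv", write_occurrence_csv)
  emit(tpm, "abundance_tpm.csv", write_abundance_csv)

  rich <- richness(occ, design)
  emit(rich, "richness.csv")
  rar <- rarefaction(occ, config$n_rarefaction, seed = config$seed)
  emit(data.frame(k = rar$k, mean_richness = rar$mean_richness),
       "rarefaction.csv")
  mw <- pairwise_richness_tests(rich)
  emit(mw, "richness_tests.csv")

  bc <- bray_curtis(tpm)
  emit(bc, "bray_curtis.csv", write_dissimilarity_csv)
  ord <- nmds(bc, k = 2, seed = config$seed)
  emit(data.frame(sample_id = rownames(ord$points), ord$points,
                  stress = ord$stress), "nmds.csv")
  i <- match(colnames(occ), design$sample_id)
  perm_pheno <- permanova(bc, design$phenotype[i],
                          config$n_permanova, seed = config$seed)
  perm_comp <- permanova(bc, design$compartment[i],
                         config$n_permanova, seed = config$seed)
  emit(data.frame(term = c("phenotype", "compartment"),
                  F = c(perm_pheno$F, perm_comp$F),
                  R2 = c(perm_pheno$R2, perm_comp$R2),
                  p_value = c(perm_pheno$p_value, perm_comp$p_value),
                  n_permutations = config$n_permanova),
       "permanova.csv")
  message("diversity stage: total richness ",
          sum(rowSums(occ) > 0), ", NMDS stress ", round(ord$stress, 4))

  nm_pheno <- null_model(occ, design, "phenotype", config$n_null,
                         config$null_mode, seed = config$seed)
  nm_comp <- null_model(occ, design, "compartment", config$n_null,
                        config$null_mode, seed = config$seed)
  emit(rbind(cbind(classification = "phenotype", sharing_class_table(nm_pheno)),
             cbind(classification = "compartment", sharing_class_table(nm_comp))),
       "sharing_classes.csv")
  emit(data.frame(classification = c("phenotype", "compartment"),
                  chi2 = c(nm_pheno$chi2, nm_comp$chi2),
                  df = c(nm_pheno$df, nm_comp$df),
                  p_value = c(nm_pheno$p_value, nm_comp$p_value),
                  n_replicates = config$n_null),
       "null_model_tests.csv")
  message("co-occurrence stage: ", sum(nm_pheno$observed),
          " multi-sample vOTUs")

  annot <- NULL
  if (is.null(genes) && simulate_annotation) {
    genes <- generate_gene_tables(seed = config$seed)
  }
  if (is.null(hosts) && simulate_annotation) {
    orders <- data.frame(
      order = sprintf("order_%02d", 1:22),
      phylum = sprintf("phylum_%02d", rep(1:14, length.out = 22)))
    hosts <- generate_host_table(rownames(occ), orders, p_assigned = 0.083,
                                 seed = config$seed)
    if (is.null(functions)) {
      functions <- data.frame(
        order = orders$order[1:9],
        func = rep(c("sulfur-oxidizing", "sulfate-reducing", "iron-oxidizing"),
                   each = 3))
    }
  }
  if (!is.null(genes) || !is.null(hosts)) {
    annot <- list()
    if (!is.null(genes)) {
      hits <- filter_hits(genes, config$min_bitscore, config$max_evalue)
      annot$amg <- flag_amg(genes, config$flank)
      emit(hits, "filtered_hits.csv")
      emit(annot$amg, "amg_candidates.csv")
    }
    if (!is.null(hosts)) {
      if (is.null(functions)) functions <- data.frame(order = character(),
                                                      func = character())
      annot$host_tags <- tag_host_functions(hosts, functions)
      annot$host_summary <- summarize_host_predictions(hosts, occ, design)
      emit(annot$host_tags$tags, "host_function_tags.csv")
      emit(annot$host_summary$cells, "host_summary_cells.csv")
      emit(annot$host_summary$phyla, "host_summary_phyla.csv")
    }
    message("annotation stage: ",
            if (!is.null(annot$amg)) nrow(annot$amg) else 0,
            " AMG candidates, ",
            if (!is.null(hosts)) nrow(hosts) else 0, " host predictions")
  }

  manifest <- list(
    config_hash = .hash_object(unclass(config)[setdiff(names(config), "sim")]),
    seed = config$seed,
    outputs = written,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(
    occurrence = occ, abundance = tpm, richness = rich, rarefaction = rar,
    richness_tests = mw, bray_curtis = bc, nmds = ord,
    permanova = list(phenotype = perm_pheno, compartment = perm_comp),
    null_model = list(phenotype = nm_pheno, compartment = nm_comp),
    annotation = annot, ground_truth = truth, manifest = manifest
  ))
}

# md5 of a serialized object via a temp file (base tools only)
.hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
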