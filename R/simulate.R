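#' Simulation parameters for the synthetic virome generator
#'
#' Bundles and validates every knob of the coverage generator. Defaults are
#' set to the study scale the package targets: 769 vOTUs over a 24-sample
#' design, strong phenotype fidelity, and a compartment-proximity gradient in
#' which bulk sediment and root never share a vOTU without the rhizosphere.
#'
#' @param n_votus number of viral populations to simulate.
#' @param contig_length_range bp interval for contig lengths (min >= 5000);
#'   lengths are drawn log-uniformly so the TPM length correction is
#'   exercised by heterogeneous contigs.
#' @param phenotype_fidelity probability in \[0,1\] that a vOTU is restricted
#'   to a single plant phenotype.
#' @param compartment_weights named non-negative weights over the 7
#'   compartment sharing classes (see [COMPARTMENT_CLASSES]); each vOTU's
#'   eligible compartments are drawn from these. The default puts weight 0 on
#'   "bulk+root", encoding the proximity constraint that bulk and root only
#'   share viruses via the rhizosphere.
#' @param per_sample_occupancy probability that a vOTU occupies each of its
#'   eligible samples.
#' @param depth_mean mean read depth (x coverage) for present (vOTU, sample)
#'   pairs.
#' @param depth_dispersion negative-binomial dispersion for read counts of
#'   present pairs (variance = mu + dispersion * mu^2).
#' @param background_depth mean depth over the covered fraction for absent
#'   pairs (spurious mapping).
#' @param background_breadth_max upper bound (< 0.75) of the breadth
#'   distribution for absent pairs; the gap up to the presence threshold
#'   keeps ground-truth occupancy exactly recoverable.
#' @param read_length read length in bp used to convert depth to read counts.
#' @param seed integer seed.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_votus = 769,
                       contig_length_range = c(5000, 60000),
                       phenotype_fidelity = 0.8,
                       compartment_weights = c(
                         "bulk-only" = 0.10, "rhizosphere-only" = 0.05,
                         "root-only" = 0.05, "bulk+rhizosphere" = 0.20,
                         "rhizosphere+root" = 0.30, "bulk+root" = 0.00,
                         "all-three" = 0.30),
                       per_sample_occupancy = 0.35,
                       depth_mean = 5,
                       depth_dispersion = 0.5,
                       background_depth = 0.5,
                       background_breadth_max = 0.70,
                       read_length = 150,
                       seed = 1L) {
  stopifnot(length(n_votus) == 1, n_votus >= 1, n_votus == round(n_votus))
  if (length(contig_length_range) != 2 || contig_length_range[1] < 5000 ||
      diff(contig_length_range) < 0) {
    stop("contig_length_range must be an increasing bp interval with min >= 5000")
  }
  .check_prob <- function(p, what) {
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      stop(what, " must be a probability in [0, 1]")
    }
  }
  .check_prob(phenotype_fidelity, "phenotype_fidelity")
  .check_prob(per_sample_occupancy, "per_sample_occupancy")
  if (!setequal(names(compartment_weights), COMPARTMENT_CLASSES)) {
    stop("compartment_weights must be named by the 7 compartment classes")
  }
  compartment_weights <- compartment_weights[COMPARTMENT_CLASSES]
  if (any(compartment_weights < 0) || sum(compartment_weights) <= 0) {
    stop("compartment_weights must be non-negative with positive sum")
  }
  if (background_breadth_max >= 0.75) {
    stop("background_breadth_max must stay below the 0.75 presence threshold")
  }
  stopifnot(depth_mean > 0, depth_dispersion >= 0, background_depth >= 0,
            read_length >= 1)
  structure(list(
    n_votus = as.integer(n_votus),
    contig_length_range = contig_length_range,
    phenotype_fidelity = phenotype_fidelity,
    compartment_weights = compartment_weights / sum(compartment_weights),
    per_sample_occupancy = per_sample_occupancy,
    depth_mean = depth_mean,
    depth_dispersion = depth_dispersion,
    background_depth = background_depth,
    background_breadth_max = background_breadth_max,
    read_length = read_length,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Simulate per-(vOTU, sample) mapping coverage with known occupancy
#'
#' Draws, for every vOTU and sample, a contig length, covered bases and a
#' mapped read count, under a ground-truth occupancy model with phenotype
#' fidelity and a compartment-proximity gradient. Present pairs get breadth
#' of coverage in \[0.75, 1\]; absent pairs stay strictly below
#' `background_breadth_max`, so [call_presence()] recovers the ground truth
#' exactly.
#'
#' Occupancy model, per vOTU: with probability `phenotype_fidelity` the vOTU
#' is restricted to one phenotype (chosen uniformly); a compartment sharing
#' class is drawn from `compartment_weights`; each eligible sample (allowed
#' phenotype and compartment) is occupied independently with probability
#' `per_sample_occupancy`. For "all-three" vOTUs whose realized occupancy
#' hits bulk and root but misses the rhizosphere, one eligible rhizosphere
#' sample is force-occupied, so exclusive bulk+root sharing can only arise
#' from positive weight on that class.
#'
#' @param design sample table from [generate_design()].
#' @param params [sim_params()] object.
#' @return list with `coverage` (long data.frame: votu_id, sample_id,
#'   contig_length, covered_bases, mapped_reads), `occupancy` (ground-truth
#'   logical vOTU x sample matrix), and `votus` (per-vOTU table with contig
#'   length and the latent phenotype/compartment eligibility).
#' @export
generate_coverage <- function(design, params = sim_params()) {
  .check_design(design)
  if (!inherits(params, "sim_params")) stop("params must come from sim_params()")
  set.seed(params$seed)
  n_v <- params$n_votus
  n_s <- nrow(design)
  votu_ids <- sprintf("vOTU_%04d", seq_len(n_v))

  lr <- log(params$contig_length_range)
  lengths <- as.integer(round(exp(stats::runif(n_v, lr[1], lr[2]))))

  restricted <- stats::runif(n_v) < params$phenotype_fidelity
  pheno_pick <- sample(PHENOTYPES, n_v, replace = TRUE)
  comp_class <- sample(COMPARTMENT_CLASSES, n_v, replace = TRUE,
                       prob = params$compartment_weights)

  occupancy <- matrix(FALSE, n_v, n_s, dimnames = list(votu_ids, design$sample_id))
  for (i in seq_len(n_v)) {
    ok_pheno <- if (restricted[i]) design$phenotype == pheno_pick[i] else rep(TRUE, n_s)
    ok_comp <- design$compartment %in% .compartment_class_sets[[comp_class[i]]]
    eligible <- which(ok_pheno & ok_comp)
    occ <- eligible[stats::runif(length(eligible)) < params$per_sample_occupancy]
    # proximity repair: an all-three vOTU seen in bulk and root must also be
    # seen in the rhizosphere (bulk<->root sharing goes through it)
    comps_hit <- unique(design$compartment[occ])
    if (all(c("bulk", "root") %in% comps_hit) && !("rhizosphere" %in% comps_hit)) {
      rhizo <- eligible[design$compartment[eligible] == "rhizosphere"]
      if (length(rhizo) > 0) occ <- c(occ, rhizo[sample.int(length(rhizo), 1)])
    }
    occupancy[i, occ] <- TRUE
  }

  # long coverage table over every (vOTU, sample) pair
  present <- as.vector(occupancy)
  len_v <- rep(lengths, times = n_s)
  n_pair <- n_v * n_s
  breadth <- numeric(n_pair)
  breadth[present] <- stats::runif(sum(present), 0.75, 1)
  breadth[!present] <- stats::runif(sum(!present), 0, params$background_breadth_max)
  covered <- integer(n_pair)
  covered[present] <- pmin(len_v[present],
                           as.integer(ceiling(breadth[present] * len_v[present])))
  covered[!present] <- as.integer(floor(breadth[!present] * len_v[!present]))

  # dispersion 0 degenerates to Poisson depth
  .rcounts <- function(n, mu) {
    if (params$depth_dispersion > 0) {
      stats::rnbinom(n, mu = mu, size = 1 / params$depth_dispersion)
    } else {
      stats::rpois(n, mu)
    }
  }
  reads <- integer(n_pair)
  if (any(present)) {
    mu_p <- params$depth_mean * len_v[present] / params$read_length
    reads[present] <- pmax(1L, .rcounts(sum(present), mu_p))
  }
  bg <- !present & covered > 0
  if (any(bg)) {
    mu_b <- pmax(params$background_depth * covered[bg] / params$read_length, 0.1)
    reads[bg] <- pmax(1L, .rcounts(sum(bg), mu_b))
  }

  coverage <- data.frame(
    votu_id = rep(votu_ids, times = n_s),
    sample_id = rep(design$sample_id, each = n_v),
    contig_length = len_v,
    covered_bases = covered,
    mapped_reads = reads,
    stringsAsFactors = FALSE
  )
  votus <- data.frame(
    votu_id = votu_ids,
    contig_length = lengths,
    phenotype_restricted = restricted,
    phenotype = ifelse(restricted, pheno_pick, "both"),
    compartment_class = comp_class,
    stringsAsFactors = FALSE
  )
  list(coverage = coverage, occupancy = occupancy, votus = votus)
}

#' Simulate ordered per-contig gene annotation tables
#'
#' Emulates the tabular output of gene prediction + HMM annotation: for each
#' contig an ordered list of genes labelled viral, metabolic or unknown, with
#' bit scores and e-values scattered around the hit-filter thresholds (bit
#' score 30, e-value 0.01) so both sides of the filter are populated.
#'
#' @param n_contigs number of contigs.
#' @param genes_per_contig single count or length-2 range (sampled uniformly).
#' @param p_viral,p_metabolic per-gene class probabilities; remainder is
#'   "unknown" (`p_viral + p_metabolic <= 1`).
#' @param seed integer seed.
#' @return data.frame: contig_id, gene_index (1-based, consecutive),
#'   annotation_class, bit_score, e_value.
#' @export
generate_gene_tables <- function(n_contigs = 50, genes_per_contig = c(5, 30),
                                 p_viral = 0.6, p_metabolic = 0.05,
                                 seed = 1L) {
  stopifnot(n_contigs >= 1, p_viral >= 0, p_metabolic >= 0)
  if (p_viral + p_metabolic > 1) stop("p_viral + p_metabolic must be <= 1")
  set.seed(seed)
  if (length(genes_per_contig) == 1) genes_per_contig <- rep(genes_per_contig, 2)
  n_genes <- sample(genes_per_contig[1]:genes_per_contig[2], n_contigs,
                    replace = TRUE)
  contig_id <- rep(sprintf("contig_%03d", seq_len(n_contigs)), times = n_genes)
  total <- sum(n_genes)
  cls <- sample(c("viral", "metabolic", "unknown"), total, replace = TRUE,
                prob = c(p_viral, p_metabolic, 1 - p_viral - p_metabolic))
  data.frame(
    contig_id = contig_id,
    gene_index = unlist(lapply(n_genes, seq_len), use.names = FALSE),
    annotation_class = cls,
    bit_score = round(stats::runif(total, 10, 60), 1),
    e_value = 10^stats::runif(total, -10, 0),
    stringsAsFactors = FALSE
  )
}

#' Simulate a phage host-prediction table
#'
#' Emulates order-level host predictions where only a fraction of vOTUs
#' receive a (single) prediction, as is typical for environmental viromes.
#'
#' @param votu_ids character vector of vOTU identifiers.
#' @param orders data.frame with columns `order`, `phylum`, or a character
#'   vector of order names (phyla then synthesized one per order).
#' @param p_assigned probability each vOTU receives a host prediction.
#' @param seed integer seed.
#' @return data.frame: votu_id, host_phylum, host_order — one row per
#'   assigned vOTU (zero rows when nothing is assigned).
#' @export
generate_host_table <- function(votu_ids, orders, p_assigned = 0.083,
                                seed = 1L) {
  if (!is.numeric(p_assigned) || p_assigned < 0 || p_assigned > 1) {
    stop("p_assigned must be a probability in [0, 1]")
  }
  if (is.character(orders)) {
    orders <- data.frame(order = orders,
                         phylum = paste0("phylum_of_", orders),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("order", "phylum") %in% names(orders)), nrow(orders) >= 1)
  set.seed(seed)
  assigned <- stats::runif(length(votu_ids)) < p_assigned
  idx <- sample.int(nrow(orders), sum(assigned), replace = TRUE)
  data.frame(
    votu_id = votu_ids[assigned],
    host_phylum = orders$phylum[idx],
    host_order = orders$order[idx],
    stringsAsFactors = FALSE
  )
}
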