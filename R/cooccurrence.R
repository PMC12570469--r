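#' Restrict an occurrence matrix to multi-sample vOTUs
#'
#' Sharing-class analysis only concerns vOTUs found in two or more samples;
#' this keeps exactly the rows with >= 2 presences.
#'
#' @param occ logical occurrence matrix (vOTUs x samples).
#' @return the multi-sample subset of `occ` (possibly zero rows).
#' @export
multi_sample_filter <- function(occ) {
  stopifnot(is.matrix(occ), is.logical(occ))
  occ[rowSums(occ) >= 2, , drop = FALSE]
}

# classify each vOTU of a (multi-sample) occurrence matrix into sharing
# classes; vectorized over vOTUs
.classify <- function(occ_multi, design, classification) {
  .check_design(design)
  unknown <- setdiff(colnames(occ_multi), design$sample_id)
  if (length(unknown) > 0) {
    stop("samples not in design: ", paste(unknown, collapse = ", "))
  }
  lab <- if (classification == "phenotype") design$phenotype else design$compartment
  lab <- lab[match(colnames(occ_multi), design$sample_id)]
  if (classification == "phenotype") {
    in_short <- rowSums(occ_multi[, lab == "short", drop = FALSE]) > 0
    in_tall <- rowSums(occ_multi[, lab == "tall", drop = FALSE]) > 0
    cls <- ifelse(in_short & in_tall, "both-phenotypes",
                  ifelse(in_short, "short-only", "tall-only"))
    levels <- PHENOTYPE_CLASSES
  } else {
    in_b <- rowSums(occ_multi[, lab == "bulk", drop = FALSE]) > 0
    in_rz <- rowSums(occ_multi[, lab == "rhizosphere", drop = FALSE]) > 0
    in_rt <- rowSums(occ_multi[, lab == "root", drop = FALSE]) > 0
    key <- paste0(in_b + 0, in_rz + 0, in_rt + 0)
    map <- c("100" = "bulk-only", "010" = "rhizosphere-only",
             "001" = "root-only", "110" = "bulk+rhizosphere",
             "011" = "rhizosphere+root", "101" = "bulk+root",
             "111" = "all-three")
    cls <- unname(map[key])
    levels <- COMPARTMENT_CLASSES
  }
  factor(cls, levels = levels)
}

# build a sharing_classes result from a per-vOTU class factor
.sharing_result <- function(cls, votu_ids, classification) {
  counts <- table(cls)
  structure(list(
    classification = classification,
    classes = setNames(as.character(cls), votu_ids),
    counts = setNames(as.integer(counts), names(counts)),
    n_multi = length(cls)
  ), class = "sharing_classes")
}

#' Classify multi-sample vOTUs by the phenotypes they span
#'
#' Maps each multi-sample vOTU to the set of plant phenotypes of the
#' samples it occupies: `short-only`, `tall-only` or `both-phenotypes`.
#'
#' @param occ_multi multi-sample occurrence matrix
#'   (see [multi_sample_filter()]).
#' @param design sample table with phenotype labels.
#' @return list of class `sharing_classes` with per-vOTU `classes`, class
#'   `counts` (summing to `n_multi`), and `n_multi`.
#' @export
classify_phenotype_sharing <- function(occ_multi, design) {
  cls <- .classify(occ_multi, design, "phenotype")
  .sharing_result(cls, rownames(occ_multi), "phenotype")
}

#' Classify multi-sample vOTUs by the compartments they span
#'
#' Maps each multi-sample vOTU to one of the 7 compartment sharing classes
#' (three exclusive, three pairwise, all-three).
#'
#' @inheritParams classify_phenotype_sharing
#' @return list of class `sharing_classes` (see
#'   [classify_phenotype_sharing()]).
#' @export
classify_compartment_sharing <- function(occ_multi, design) {
  cls <- .classify(occ_multi, design, "compartment")
  .sharing_result(cls, rownames(occ_multi), "compartment")
}

#' Richness-conserving randomization null model for sharing classes
#'
#' Generates the expected sharing-class distribution under no niche
#' structure: in each replicate every sample is reassigned a uniformly
#' random subset of vOTU identities — drawn without replacement from the
#' full catalog of vOTUs ever observed — of size equal to that sample's
#' observed richness (`mode = "per_sample"`, default). The multi-sample
#' filter and the classification are then recomputed on the randomized
#' matrix. The alternative `mode = "per_cell"` pools occurrences within
#' each phenotype x compartment cell and redraws that many (vOTU, sample)
#' incidences cell-wide, conserving cell-level incidence counts instead of
#' per-sample richness.
#'
#' Expected class proportions are pooled across replicates (total class
#' counts over total multi-sample counts); a chi-squared goodness-of-fit
#' test compares the observed class counts to these proportions scaled to
#' the observed multi-sample total.
#'
#' @param occ logical occurrence matrix (the full catalog: every vOTU ever
#'   observed, including single-sample ones).
#' @param design sample table.
#' @param classification "phenotype" or "compartment".
#' @param n_replicates number of randomized replicates.
#' @param mode "per_sample" (default) or "per_cell".
#' @param seed integer seed.
#' @return list of class `null_model_result`: `observed` (class counts),
#'   `expected_counts` (mean per-replicate class counts),
#'   `expected_proportions` (pooled), `replicate_counts`
#'   (n_replicates x classes), `replicate_n_multi`, `chi2`, `df`,
#'   `p_value`, `n_replicates`, `mode`, `seed`.
#' @export
null_model <- function(occ, design, classification = c("phenotype", "compartment"),
                       n_replicates = 1000, mode = c("per_sample", "per_cell"),
                       seed = NULL) {
  classification <- match.arg(classification)
  mode <- match.arg(mode)
  stopifnot(is.matrix(occ), is.logical(occ), n_replicates >= 1)
  .check_design(design)
  n_votu <- nrow(occ)
  n_samp <- ncol(occ)
  rich <- colSums(occ)
  if (any(rich > n_votu)) stop("sample richness exceeds catalog size")
  if (!is.null(seed)) set.seed(seed)

  obs <- .classify(multi_sample_filter(occ), design, classification)
  obs_counts <- setNames(as.integer(table(obs)), levels(obs))
  classes <- levels(obs)

  cell <- paste(design$phenotype[match(colnames(occ), design$sample_id)],
                design$compartment[match(colnames(occ), design$sample_id)])
  cell_pairs <- if (mode == "per_cell") {
    lapply(unique(cell), function(cl) {
      cols <- which(cell == cl)
      list(cols = cols, n_inc = sum(rich[cols]))
    })
  }

  rep_counts <- matrix(0L, n_replicates, length(classes),
                       dimnames = list(NULL, classes))
  rep_multi <- integer(n_replicates)
  m <- matrix(FALSE, n_votu, n_samp,
              dimnames = list(rownames(occ), colnames(occ)))
  for (r in seq_len(n_replicates)) {
    m[] <- FALSE
    if (mode == "per_sample") {
      for (s in seq_len(n_samp)) {
        if (rich[s] > 0) m[sample.int(n_votu, rich[s]), s] <- TRUE
      }
    } else {
      for (cp in cell_pairs) {
        n_slots <- n_votu * length(cp$cols)
        if (cp$n_inc > n_slots) stop("cell incidence exceeds available slots")
        if (cp$n_inc > 0) {
          pick <- sample.int(n_slots, cp$n_inc)
          m[cbind((pick - 1) %% n_votu + 1,
                  cp$cols[(pick - 1) %/% n_votu + 1])] <- TRUE
        }
      }
    }
    cls <- .classify(multi_sample_filter(m), design, classification)
    rep_counts[r, ] <- as.integer(table(cls))
    rep_multi[r] <- length(cls)
  }

  total <- colSums(rep_counts)
  expected_prop <- if (sum(total) > 0) total / sum(total) else
    setNames(rep(NA_real_, length(classes)), classes)
  gof <- if (sum(obs_counts) > 0 && !anyNA(expected_prop)) {
    chi_square_gof(obs_counts, expected_prop)
  } else {
    list(chi2 = NA_real_, df = NA_integer_, p_value = NA_real_,
         infinite = FALSE)
  }
  structure(list(
    classification = classification,
    observed = obs_counts,
    expected_counts = colMeans(rep_counts),
    expected_proportions = expected_prop,
    replicate_counts = rep_counts,
    replicate_n_multi = rep_multi,
    chi2 = gof$chi2, df = gof$df, p_value = gof$p_value,
    infinite = isTRUE(gof$infinite),
    n_replicates = as.integer(n_replicates),
    mode = mode, seed = seed
  ), class = "null_model_result")
}

#' Exact sharing-class expectations by exhaustive enumeration
#'
#' Independent oracle for [null_model()] on tiny instances: enumerates every
#' combination of per-sample vOTU subsets of the observed richnesses, and
#' averages the sharing-class counts of the multi-sample set over all
#' combinations. Refuses instances with more than 10^6 combinations.
#'
#' @param sample_richnesses named integer vector (sample_id -> richness).
#' @param catalog_size number of vOTUs in the catalog.
#' @param design sample table covering the named samples.
#' @param classification "phenotype" or "compartment".
#' @return list: `expected_counts` (expected per-replicate class counts),
#'   `expected_proportions` (pooled, NA if multi-sample sets are always
#'   empty), `expected_n_multi`, `n_combinations`.
#' @export
exact_null_expectations <- function(sample_richnesses, catalog_size, design,
                                    classification = c("phenotype", "compartment")) {
  classification <- match.arg(classification)
  .check_design(design)
  stopifnot(!is.null(names(sample_richnesses)), catalog_size >= 1,
            all(sample_richnesses >= 0))
  if (any(sample_richnesses > catalog_size)) {
    stop("sample richness exceeds catalog size")
  }
  n_comb <- prod(choose(catalog_size, sample_richnesses))
  if (n_comb > 1e6) {
    stop("instance too large for exhaustive enumeration (", format(n_comb),
         " > 1e6 combinations)")
  }
  samples <- names(sample_richnesses)
  subsets <- lapply(sample_richnesses, function(r) {
    if (r == 0) list(integer(0)) else
      asplit(utils::combn(catalog_size, r), 2)
  })
  classes <- if (classification == "phenotype") PHENOTYPE_CLASSES else
    COMPARTMENT_CLASSES
  acc <- setNames(numeric(length(classes)), classes)
  acc_multi <- 0
  n_seen <- 0
  m <- matrix(FALSE, catalog_size, length(samples),
              dimnames = list(paste0("v", seq_len(catalog_size)), samples))
  idx <- rep(1L, length(samples))
  sizes <- vapply(subsets, length, integer(1))
  repeat {
    m[] <- FALSE
    for (s in seq_along(samples)) m[subsets[[s]][[idx[s]]], s] <- TRUE
    cls <- .classify(multi_sample_filter(m), design, classification)
    acc <- acc + as.integer(table(cls))
    acc_multi <- acc_multi + length(cls)
    n_seen <- n_seen + 1
    # odometer increment over the cartesian product
    s <- 1L
    while (s <= length(samples)) {
      idx[s] <- idx[s] + 1L
      if (idx[s] <= sizes[s]) break
      idx[s] <- 1L
      s <- s + 1L
    }
    if (s > length(samples)) break
  }
  list(
    expected_counts = acc / n_seen,
    expected_proportions = if (acc_multi > 0) acc / acc_multi else
      setNames(rep(NA_real_, length(classes)), classes),
    expected_n_multi = acc_multi / n_seen,
    n_combinations = n_seen
  )
}

#' Chi-squared goodness-of-fit of class counts against expected proportions
#'
#' Pearson chi-squared test of observed sharing-class counts against
#' expected counts = proportions x total observed. Classes with expected
#' proportion 0 and observed count 0 are dropped from the degrees of
#' freedom; an expected 0 with a positive observed count is flagged as an
#' infinite statistic.
#'
#' @param observed_counts non-negative integer vector (sum > 0).
#' @param expected_proportions non-negative vector summing to 1.
#' @return list: `chi2`, `df`, `p_value`, `infinite`, `expected_counts`.
#'   A warning is raised when any kept expected count is below 5.
#' @export
chi_square_gof <- function(observed_counts, expected_proportions) {
  stopifnot(length(observed_counts) == length(expected_proportions),
            all(observed_counts >= 0), all(expected_proportions >= 0))
  n <- sum(observed_counts)
  if (n <= 0) stop("observed counts must sum to > 0")
  if (abs(sum(expected_proportions) - 1) > 1e-8) {
    stop("expected proportions must sum to 1")
  }
  expected <- expected_proportions * n
  impossible <- expected_proportions == 0 & observed_counts > 0
  if (any(impossible)) {
    return(list(chi2 = Inf, df = NA_integer_, p_value = 0, infinite = TRUE,
                expected_counts = expected))
  }
  keep <- !(expected_proportions == 0 & observed_counts == 0)
  o <- observed_counts[keep]
  e <- expected[keep]
  if (any(e < 5)) warning("expected count below 5 in ", sum(e < 5),
                          " class(es); chi-squared approximation may be poor")
  chi2 <- sum((o - e)^2 / e)
  df <- sum(keep) - 1L
  list(chi2 = chi2, df = as.integer(df),
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       infinite = FALSE, expected_counts = expected)
}

#' Tidy observed-vs-expected sharing-class table
#'
#' @param nm a `null_model_result` from [null_model()].
#' @return data.frame: class, observed, observed_pct, expected,
#'   expected_proportion.
#' @export
sharing_class_table <- function(nm) {
  stopifnot(inherits(nm, "null_model_result"))
  n <- sum(nm$observed)
  data.frame(
    class = names(nm$observed),
    observed = as.integer(nm$observed),
    observed_pct = if (n > 0) 100 * nm$observed / n else NA_real_,
    expected = nm$expected_proportions * n,
    expected_proportion = nm$expected_proportions,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
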