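#' Filter a contig catalog by minimum length
#'
#' Viral population catalogs conventionally drop short contigs before
#' dereplication; the default keeps contigs of at least 5,000 bp
#' (inclusive).
#'
#' @param catalog data.frame with a `length` column (bp).
#' @param min_length minimum contig length in bp, inclusive.
#' @return the rows of `catalog` with `length >= min_length`.
#' @export
filter_min_length <- function(catalog, min_length = 5000) {
  stopifnot(is.data.frame(catalog), "length" %in% names(catalog))
  if (nrow(catalog) == 0) return(catalog)
  if (any(catalog$length <= 0)) stop("contig lengths must be positive")
  catalog[catalog$length >= min_length, , drop = FALSE]
}

#' Greedy longest-first dereplication into viral populations
#'
#' Clusters sequences into populations from a precomputed pairwise
#' similarity table, following the convention used to delineate dsDNA viral
#' populations: sequences qualify as the same population at >= 95% average
#' nucleotide identity over >= 80% alignment coverage (of the shorter
#' sequence), and the longest member represents each population.
#'
#' The algorithm is greedy longest-first: sequences are visited in order of
#' decreasing length (ties broken by id); each sequence joins the first
#' existing cluster whose representative it matches at both thresholds,
#' otherwise it founds a new cluster. Representatives are therefore always
#' the founding (longest) member.
#'
#' @param catalog data.frame with columns `seq_id`, `length`.
#' @param pairs data.frame with columns `seq_a`, `seq_b`, `identity`,
#'   `coverage` (fractions in \[0,1\]); treated as symmetric.
#' @param id_threshold minimum identity, inclusive.
#' @param cov_threshold minimum alignment coverage, inclusive.
#' @return data.frame with columns `seq_id`, `length`, `cluster`,
#'   `representative`, `is_representative`; one row per input sequence.
#' @export
dereplicate <- function(catalog, pairs, id_threshold = 0.95,
                        cov_threshold = 0.80) {
  stopifnot(is.data.frame(catalog),
            all(c("seq_id", "length") %in% names(catalog)))
  if (anyDuplicated(catalog$seq_id)) stop("duplicate seq_id in catalog")
  if (nrow(pairs) > 0) {
    stopifnot(all(c("seq_a", "seq_b", "identity", "coverage") %in% names(pairs)))
    unknown <- setdiff(unique(c(pairs$seq_a, pairs$seq_b)), catalog$seq_id)
    if (length(unknown) > 0) {
      stop("pairs reference ids with unknown lengths: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
  }

  ord <- order(-catalog$length, catalog$seq_id)
  ids <- catalog$seq_id[ord]

  # symmetric qualifying-match lookup
  q <- pairs[pairs$identity >= id_threshold & pairs$coverage >= cov_threshold, ,
             drop = FALSE]
  match_key <- unique(c(paste(q$seq_a, q$seq_b), paste(q$seq_b, q$seq_a)))

  rep_of <- character(0)          # cluster representatives, founding order
  cluster <- setNames(character(length(ids)), ids)
  for (id in ids) {
    hit <- NA_character_
    for (r in rep_of) {
      if (paste(id, r) %in% match_key) { hit <- r; break }
    }
    if (is.na(hit)) {
      rep_of <- c(rep_of, id)
      cluster[id] <- id
    } else {
      cluster[id] <- hit
    }
  }

  out <- catalog
  out$cluster <- match(cluster[out$seq_id], rep_of)
  out$representative <- cluster[out$seq_id]
  out$is_representative <- out$seq_id == out$representative
  rownames(out) <- NULL
  out
}

#' Call vOTU presence from breadth of coverage
#'
#' A vOTU is scored present in a sample when mapping covers at least
#' `breadth_threshold` of the contig length (default >= 75%).
#'
#' @param cov coverage summary data.frame with columns `votu_id`,
#'   `sample_id`, `contig_length`, `covered_bases`.
#' @param breadth_threshold presence threshold on covered fraction,
#'   inclusive.
#' @return logical occurrence matrix, vOTUs in rows, samples in columns.
#'   (vOTU, sample) pairs missing from `cov` are absent.
#' @export
call_presence <- function(cov, breadth_threshold = 0.75) {
  .check_coverage(cov)
  votus <- sort(unique(cov$votu_id))
  samples <- sort(unique(cov$sample_id))
  occ <- matrix(FALSE, length(votus), length(samples),
                dimnames = list(votus, samples))
  present <- cov$covered_bases / cov$contig_length >= breadth_threshold
  occ[cbind(match(cov$votu_id, votus),
            match(cov$sample_id, samples))] <- present
  occ
}

#' Relative abundance as transcripts per million (TPM)
#'
#' Length-normalized read-count abundance: per sample, each vOTU's read
#' count is divided by its contig length in kb, and the resulting rates are
#' scaled to sum to 10^6. Samples with no mapped reads yield an all-zero
#' column.
#'
#' @param cov coverage summary data.frame (see [call_presence()]) including
#'   `mapped_reads`.
#' @param mask_absent if TRUE, reads on vOTUs that fail the presence call
#'   are zeroed before normalization, so only present vOTUs share the
#'   million. Default FALSE: presence and abundance are computed as separate
#'   steps and every vOTU with mapped reads enters the denominator.
#' @param breadth_threshold presence threshold used when `mask_absent`.
#' @return numeric TPM matrix, vOTUs in rows, samples in columns; each
#'   column sums to 10^6 or 0.
#' @export
compute_tpm <- function(cov, mask_absent = FALSE, breadth_threshold = 0.75) {
  .check_coverage(cov)
  votus <- sort(unique(cov$votu_id))
  samples <- sort(unique(cov$sample_id))
  rate <- matrix(0, length(votus), length(samples),
                 dimnames = list(votus, samples))
  r <- cov$mapped_reads / (cov$contig_length / 1000)
  rate[cbind(match(cov$votu_id, votus), match(cov$sample_id, samples))] <- r
  if (mask_absent) {
    occ <- call_presence(cov, breadth_threshold)
    rate[!occ[votus, samples, drop = FALSE]] <- 0
  }
  totals <- colSums(rate)
  nz <- totals > 0
  rate[, nz] <- sweep(rate[, nz, drop = FALSE], 2, totals[nz], "/") * 1e6
  rate
}

# shared validation of the long coverage summary
.check_coverage <- function(cov) {
  req <- c("votu_id", "sample_id", "contig_length", "covered_bases")
  if (!is.data.frame(cov) || !all(req %in% names(cov))) {
    stop("coverage summary needs columns: ", paste(req, collapse = ", "))
  }
  if (any(cov$contig_length <= 0)) stop("contig_length must be positive")
  if (any(cov$covered_bases < 0 | cov$covered_bases > cov$contig_length)) {
    stop("covered_bases must lie in [0, contig_length]")
  }
  if (anyDuplicated(paste(cov$votu_id, cov$sample_id))) {
    stop("coverage summary must have one row per (votu_id, sample_id)")
  }
  invisible(cov)
}
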