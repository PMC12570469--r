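#' Filter HMM annotation hits by bit score and e-value
#'
#' Keeps hits with bit score strictly above `min_bitscore` and e-value at or
#' below `max_evalue` (score bound exclusive, e-value cutoff inclusive).
#' Rows with missing scores never pass.
#'
#' @param hits data.frame with numeric `bit_score` and `e_value` columns.
#' @param min_bitscore exclusive lower bound on bit score.
#' @param max_evalue inclusive upper bound on e-value.
#' @return the retained rows of `hits`.
#' @export
filter_hits <- function(hits, min_bitscore = 30, max_evalue = 0.01) {
  stopifnot(is.data.frame(hits),
            all(c("bit_score", "e_value") %in% names(hits)))
  keep <- !is.na(hits$bit_score) & !is.na(hits$e_value) &
    hits$bit_score > min_bitscore & hits$e_value <= max_evalue
  hits[keep, , drop = FALSE]
}

#' Positional filter for auxiliary metabolic gene (AMG) candidates
#'
#' A metabolic gene on a viral contig only qualifies as an AMG candidate if
#' it sits in the interior of the contig — not among the first or last
#' `flank` genes — and its `flank` nearest neighbors on BOTH sides are
#' annotated as viral. This guards against host contamination at contig
#' ends being mistaken for virus-encoded metabolism.
#'
#' @param genes ordered gene table: columns `contig_id`, `gene_index`
#'   (1-based, consecutive within contig), `annotation_class` (one of
#'   "viral", "metabolic", "unknown").
#' @param flank number of interior/neighbor genes required on each side.
#' @return the rows of `genes` flagged as AMG candidates (possibly none).
#'   Contigs too short to have an interior (< 2 * flank + 1 genes) are
#'   skipped with a message.
#' @export
flag_amg <- function(genes, flank = 1) {
  stopifnot(is.data.frame(genes),
            all(c("contig_id", "gene_index", "annotation_class") %in% names(genes)),
            flank >= 1)
  out <- vector("list", 0)
  for (cid in unique(genes$contig_id)) {
    g <- genes[genes$contig_id == cid, , drop = FALSE]
    g <- g[order(g$gene_index), , drop = FALSE]
    if (!identical(as.integer(g$gene_index), seq_len(nrow(g)))) {
      stop("gene_index must be consecutive from 1 within contig ", cid)
    }
    n <- nrow(g)
    if (n < 2 * flank + 1) {
      message("contig ", cid, " has fewer than ", 2 * flank + 1,
              " genes; no AMG candidates possible")
      next
    }
    for (p in seq(flank + 1, n - flank)) {
      if (g$annotation_class[p] != "metabolic") next
      nb <- g$annotation_class[c((p - flank):(p - 1), (p + 1):(p + flank))]
      if (all(nb == "viral")) out[[length(out) + 1]] <- g[p, , drop = FALSE]
    }
  }
  if (length(out) == 0) return(genes[0, , drop = FALSE])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tag predicted viral hosts with biogeochemical functions at order level
#'
#' Joins host predictions against a table of microbial orders with known
#' biogeochemical roles (sulfur oxidation, sulfate reduction, iron
#' oxidation, nitrification); vOTUs whose host order carries no known role
#' (or is unknown) are tagged "none".
#'
#' @param hosts host table: columns `votu_id`, `host_phylum`, `host_order`.
#' @param functions long function table: columns `order`, `func` (one row
#'   per order x function).
#' @return list: `tags` (data.frame votu_id, host_phylum, host_order,
#'   functions — semicolon-collapsed, "none" if empty) and `summary` (list:
#'   n_votus, n_phyla, n_orders, n_functional_orders,
#'   fraction_votus_functional).
#' @export
tag_host_functions <- function(hosts, functions) {
  stopifnot(all(c("votu_id", "host_phylum", "host_order") %in% names(hosts)))
  if (nrow(functions) > 0) {
    stopifnot(all(c("order", "func") %in% names(functions)))
  }
  fn_by_order <- if (nrow(functions) > 0) {
    split(functions$func, functions$order)
  } else list()
  tag1 <- function(ord) {
    f <- fn_by_order[[ord]]
    if (is.null(f) || length(f) == 0) "none" else
      paste(sort(unique(f)), collapse = ";")
  }
  tags <- hosts
  tags$functions <- vapply(as.character(hosts$host_order), tag1, character(1),
                           USE.NAMES = FALSE)
  known <- unique(hosts$host_order[!is.na(hosts$host_order) &
                                     hosts$host_order != "unknown"])
  functional_orders <- known[known %in% names(fn_by_order)]
  n <- nrow(hosts)
  list(
    tags = tags,
    summary = list(
      n_votus = n,
      n_phyla = length(unique(hosts$host_phylum)),
      n_orders = length(known),
      n_functional_orders = length(functional_orders),
      fraction_votus_functional = if (n > 0) mean(tags$functions != "none") else 0
    )
  )
}

#' Summarize host predictions per phenotype x compartment cell
#'
#' A vOTU counts toward a cell if present in at least one of that cell's
#' samples; the percentage is host-assigned vOTUs over all vOTUs present in
#' the cell.
#'
#' @param hosts host table (`votu_id`, `host_phylum`, `host_order`); must
#'   reference vOTUs present in `occ`.
#' @param occ logical occurrence matrix.
#' @param design sample table.
#' @return list: `cells` (data.frame phenotype, compartment,
#'   n_votus_present, n_with_host, pct_with_host) and `phyla` (data.frame
#'   phenotype, compartment, phylum, n_votus).
#' @export
summarize_host_predictions <- function(hosts, occ, design) {
  stopifnot(is.matrix(occ), is.logical(occ))
  .check_design(design)
  unknown <- setdiff(hosts$votu_id, rownames(occ))
  if (length(unknown) > 0) {
    stop("host table references vOTUs absent from the occurrence matrix: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  i <- match(colnames(occ), design$sample_id)
  cells <- unique(design[, c("phenotype", "compartment")])
  rows <- list(); ph_rows <- list()
  for (r in seq_len(nrow(cells))) {
    in_cell <- design$phenotype[i] == cells$phenotype[r] &
      design$compartment[i] == cells$compartment[r]
    present <- rownames(occ)[rowSums(occ[, in_cell, drop = FALSE]) > 0]
    hosted <- hosts[hosts$votu_id %in% present, , drop = FALSE]
    rows[[r]] <- data.frame(
      phenotype = cells$phenotype[r], compartment = cells$compartment[r],
      n_votus_present = length(present),
      n_with_host = nrow(hosted),
      pct_with_host = if (length(present) > 0)
        100 * nrow(hosted) / length(present) else 0,
      stringsAsFactors = FALSE
    )
    if (nrow(hosted) > 0) {
      tb <- table(hosted$host_phylum)
      ph_rows[[length(ph_rows) + 1]] <- data.frame(
        phenotype = cells$phenotype[r], compartment = cells$compartment[r],
        phylum = names(tb), n_votus = as.integer(tb),
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    cells = do.call(rbind, rows),
    phyla = if (length(ph_rows) > 0) do.call(rbind, ph_rows) else
      data.frame(phenotype = character(), compartment = character(),
                 phylum = character(), n_votus = integer())
  )
}
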