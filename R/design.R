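#' Study design constants
#'
#' The analysis assumes a two-phenotype (short/tall cordgrass growth form),
#' three-compartment (bulk sediment, rhizosphere, root) sampling design.
#' These vectors define the canonical factor levels and sharing-class labels
#' used throughout the package.
#'
#' @name design-constants
#' @keywords internal
NULL

PHENOTYPES <- c("short", "tall")
COMPARTMENTS <- c("bulk", "rhizosphere", "root")

#' Phenotype sharing classes for multi-sample vOTUs
#' @export
PHENOTYPE_CLASSES <- c("short-only", "tall-only", "both-phenotypes")

#' Compartment sharing classes for multi-sample vOTUs
#' @export
COMPARTMENT_CLASSES <- c(
  "bulk-only", "rhizosphere-only", "root-only",
  "bulk+rhizosphere", "rhizosphere+root", "bulk+root", "all-three"
)

# compartment sets behind each sharing-class label
.compartment_class_sets <- list(
  "bulk-only"        = "bulk",
  "rhizosphere-only" = "rhizosphere",
  "root-only"        = "root",
  "bulk+rhizosphere" = c("bulk", "rhizosphere"),
  "rhizosphere+root" = c("rhizosphere", "root"),
  "bulk+root"        = c("bulk", "root"),
  "all-three"        = c("bulk", "rhizosphere", "root")
)

#' Generate the crossed sampling design
#'
#' Builds the sample table for a fully crossed phenotype x compartment design
#' with `n_replicates` replicates per cell. The default of 4 replicates gives
#' the 24-sample layout (2 phenotypes x 3 compartments x 4 replicates) the
#' rest of the package assumes.
#'
#' @param n_replicates replicates per phenotype x compartment cell (>= 1).
#' @param seed unused; accepted so all generators share a signature. Sample
#'   identifiers are deterministic functions of the design cell.
#' @return data.frame with columns `sample_id`, `phenotype`, `compartment`,
#'   `replicate`.
#' @examples
#' design <- generate_design(4)
#' nrow(design) # 24
#' @export
generate_design <- function(n_replicates = 4, seed = NULL) {
  if (!is.numeric(n_replicates) || length(n_replicates) != 1 ||
      n_replicates < 1 || n_replicates != round(n_replicates)) {
    stop("n_replicates must be a single integer >= 1")
  }
  grid <- expand.grid(
    replicate = seq_len(n_replicates),
    compartment = COMPARTMENTS,
    phenotype = PHENOTYPES,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  design <- data.frame(
    sample_id = sprintf("%s_%s_r%d", grid$phenotype, grid$compartment,
                        grid$replicate),
    phenotype = grid$phenotype,
    compartment = grid$compartment,
    replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
  design[order(design$phenotype, match(design$compartment, COMPARTMENTS),
               design$replicate), , drop = FALSE] |>
    `rownames<-`(NULL)
}

# validate a design table; returns it invisibly
.check_design <- function(design) {
  req <- c("sample_id", "phenotype", "compartment")
  if (!is.data.frame(design) || !all(req %in% names(design))) {
    stop("design must be a data.frame with columns sample_id, phenotype, compartment")
  }
  if (anyDuplicated(design$sample_id)) stop("design sample_id values must be unique")
  if (!all(design$phenotype %in% PHENOTYPES)) {
    stop("design phenotype must be one of: ", paste(PHENOTYPES, collapse = ", "))
  }
  if (!all(design$compartment %in% COMPARTMENTS)) {
    stop("design compartment must be one of: ", paste(COMPARTMENTS, collapse = ", "))
  }
  invisible(design)
}
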