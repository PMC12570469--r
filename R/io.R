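#' Read a samtools-depth file into coverage summary rows
#'
#' Consumes the three-column `samtools depth` dialect (reference id, 1-based
#' position, depth). Positions with zero depth may be omitted, so contig
#' lengths must come from a companion length table — they are never inferred
#' from the maximum position. `covered_bases` counts positions with depth
#' >= 1. A depth stream does not carry the mapped read count, so
#' `mapped_reads` is estimated as `round(sum(depth) / read_length)`.
#'
#' @param path depth file (TSV, no header).
#' @param lengths data.frame with columns `votu_id`, `length` covering every
#'   reference in the file, e.g. from [read_length_table()] or
#'   [fasta_lengths()].
#' @param sample_id sample the depth file belongs to.
#' @param read_length read length used to estimate mapped reads from summed
#'   depth.
#' @return coverage summary data.frame (votu_id, sample_id, contig_length,
#'   covered_bases, mapped_reads), one row per reference in `lengths`
#'   (references absent from the file get zero coverage).
#' @export
read_depth_file <- function(path, lengths, sample_id, read_length = 150) {
  stopifnot(all(c("votu_id", "length") %in% names(lengths)))
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (nrow(dt) > 0) {
    if (ncol(dt) != 3) {
      bad <- which(utils::count.fields(path, sep = "\t") != 3)[1]
      stop("malformed depth file (expected 3 tab-separated columns) at line ",
           if (is.na(bad)) 1 else bad)
    }
    pos <- suppressWarnings(as.numeric(dt[[2]]))
    dep <- suppressWarnings(as.numeric(dt[[3]]))
    bad <- which(is.na(pos) | is.na(dep) | pos < 1 | pos != round(pos))[1]
    if (!is.na(bad)) stop("malformed depth file at line ", bad,
                          ": non-numeric or invalid position/depth")
    unknown <- setdiff(unique(dt[[1]]), lengths$votu_id)
    if (length(unknown) > 0) {
      stop("depth file references ids missing from the length table: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    over <- pos > lengths$length[match(dt[[1]], lengths$votu_id)]
    if (any(over)) stop("malformed depth file at line ", which(over)[1],
                        ": position exceeds contig length")
    keep <- dep >= 1
    cb <- tapply(keep, dt[[1]], sum)
    ds <- tapply(dep, dt[[1]], sum)
  } else {
    cb <- ds <- numeric(0)
  }
  out <- data.frame(
    votu_id = lengths$votu_id,
    sample_id = sample_id,
    contig_length = as.integer(lengths$length),
    covered_bases = 0L,
    mapped_reads = 0L,
    stringsAsFactors = FALSE
  )
  hit <- match(names(cb), out$votu_id)
  out$covered_bases[hit] <- as.integer(cb)
  out$mapped_reads[hit] <- as.integer(round(ds / read_length))
  out
}

#' Write a per-base depth file in the samtools-depth dialect
#'
#' Companion writer for [read_depth_file()]; zero-depth positions are
#' omitted, as `samtools depth` does by default.
#'
#' @param depths named list: per reference, an integer vector of per-base
#'   depths over the whole contig (length = contig length).
#' @param path output TSV path.
#' @export
write_depth_file <- function(depths, path) {
  rows <- lapply(names(depths), function(id) {
    d <- depths[[id]]
    keep <- which(d >= 1)
    if (length(keep) == 0) return(NULL)
    data.frame(id = id, pos = keep, depth = d[keep])
  })
  dt <- do.call(rbind, rows)
  if (is.null(dt)) dt <- data.frame(id = character(), pos = integer(),
                                    depth = integer())
  utils::write.table(dt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column contig length table
#' @param path TSV with columns id, length (no header).
#' @return data.frame with columns `votu_id`, `length`.
#' @export
read_length_table <- function(path) {
  dt <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("votu_id", "length"),
                          colClasses = c("character", "integer"))
  if (any(dt$length <= 0)) stop("lengths must be positive")
  dt
}

#' Extract contig lengths from a FASTA file
#' @param path FASTA path.
#' @return data.frame with columns `votu_id`, `length`.
#' @export
fasta_lengths <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("fasta_lengths() needs the Biostrings package")
  }
  w <- Biostrings::fasta.seqlengths(path)
  data.frame(votu_id = sub("\\s.*$", "", names(w)), length = as.integer(w),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read / write the long coverage summary CSV
#'
#' Header: votu_id, sample_id, contig_length, covered_bases, mapped_reads.
#' @param path CSV path.
#' @return data.frame (reader) / `path` invisibly (writer).
#' @export
read_coverage_csv <- function(path) {
  cov <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_coverage(cov)
  cov
}

#' @rdname read_coverage_csv
#' @param cov coverage summary data.frame.
#' @export
write_coverage_csv <- function(cov, path) {
  .check_coverage(cov)
  utils::write.csv(cov, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write vOTU x sample matrices as CSV
#'
#' Occurrence matrices are written as 0/1 integers, abundance matrices with
#' 6 decimal places; the first column holds vOTU ids and the header the
#' sample ids.
#'
#' @param mat matrix with vOTU rownames and sample colnames.
#' @param path CSV path.
#' @param digits decimal places for numeric matrices.
#' @return `path` invisibly (writers); matrix (readers).
#' @export
write_occurrence_csv <- function(mat, path) {
  stopifnot(is.logical(mat) || all(mat %in% c(0, 1)))
  df <- data.frame(votu_id = rownames(mat), mat + 0L, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_occurrence_csv
#' @export
read_occurrence_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE]) == 1
  rownames(m) <- df[[1]]
  m
}

#' @rdname write_occurrence_csv
#' @export
write_abundance_csv <- function(mat, path, digits = 6) {
  df <- data.frame(votu_id = rownames(mat), round(mat, digits),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_occurrence_csv
#' @export
read_abundance_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a square dissimilarity matrix as CSV with a sample header
#' @param d square matrix with dimnames.
#' @param path CSV path.
#' @export
write_dissimilarity_csv <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
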