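#' Per-sample viral richness
#'
#' Counts the vOTUs present in each sample and, when a design table is
#' supplied, attaches the phenotype/compartment labels used for the group
#' comparisons.
#'
#' @param occ logical occurrence matrix (vOTUs x samples).
#' @param design optional sample table (see [generate_design()]); every
#'   sample in `occ` must appear in it.
#' @return data.frame with columns `sample_id`, `richness` and, with a
#'   design, `phenotype`, `compartment`.
#' @export
richness <- function(occ, design = NULL) {
  stopifnot(is.matrix(occ), is.logical(occ))
  out <- data.frame(sample_id = colnames(occ), richness = colSums(occ),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(design)) {
    .check_design(design)
    unknown <- setdiff(out$sample_id, design$sample_id)
    if (length(unknown) > 0) {
      stop("samples not in design: ", paste(unknown, collapse = ", "))
    }
    i <- match(out$sample_id, design$sample_id)
    out$phenotype <- design$phenotype[i]
    out$compartment <- design$compartment[i]
  }
  out
}

#' Sample-accumulation (rarefaction) curve over permuted sample orders
#'
#' For each of `n_permutations` uniformly random sample orderings, computes
#' the cumulative number of distinct vOTUs seen after k samples, and
#' averages the curves.
#'
#' @param occ logical occurrence matrix (vOTUs x samples).
#' @param n_permutations number of random sample orderings.
#' @param seed integer seed.
#' @return list of class `rarefaction_curve`: `k` (1..N), `mean_richness`,
#'   and `curves` (n_permutations x N matrix of per-permutation cumulative
#'   richness).
#' @export
rarefaction <- function(occ, n_permutations = 100, seed = NULL) {
  stopifnot(is.matrix(occ), is.logical(occ), ncol(occ) >= 1,
            n_permutations >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(occ)
  curves <- matrix(0L, n_permutations, n)
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(n)
    m <- occ[, ord, drop = FALSE]
    # column index of first occurrence per vOTU (NA if never present)
    first <- apply(m, 1L, function(r) which(r)[1])
    curves[p, ] <- cumsum(tabulate(first, nbins = n))
  }
  structure(list(k = seq_len(n), mean_richness = colMeans(curves),
                 curves = curves),
            class = "rarefaction_curve")
}

#' Mann-Whitney U test for richness comparisons
#'
#' Two-sided rank-sum test. With both groups of size <= 8 and no ties the
#' exact null distribution of U is used (the study's n = 4 per group falls
#' here); otherwise the normal approximation with tie and continuity
#' corrections.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return list with `U` (statistic for `x`), `p_value`, and `method`
#'   ("exact" or "normal approximation").
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= 8 && length(y) <= 8 && !ties
  ht <- stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = use_exact, correct = TRUE)
  list(U = unname(ht$statistic), p_value = ht$p.value,
       method = if (use_exact) "exact" else "normal approximation")
}

#' All pairwise richness comparisons between design cells
#'
#' Runs [mann_whitney()] between every pair of phenotype x compartment
#' cells. Raw p-values are reported by default, matching the convention of
#' reporting uncorrected pairwise tests; Holm correction is available.
#'
#' @param rich richness table from [richness()] with group labels.
#' @param holm apply Holm correction across the pairwise tests.
#' @return data.frame: group_a, group_b, U, p_value (one row per pair).
#' @export
pairwise_richness_tests <- function(rich, holm = FALSE) {
  stopifnot(all(c("richness", "phenotype", "compartment") %in% names(rich)))
  cell <- paste(rich$phenotype, rich$compartment, sep = "/")
  cells <- unique(cell)
  pairs <- utils::combn(cells, 2)
  res <- apply(pairs, 2, function(p) {
    mw <- mann_whitney(rich$richness[cell == p[1]],
                       rich$richness[cell == p[2]])
    data.frame(group_a = p[1], group_b = p[2], U = mw$U,
               p_value = mw$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (holm) out$p_value <- stats::p.adjust(out$p_value, method = "holm")
  out
}

#' Bray-Curtis dissimilarity between samples
#'
#' BC(x, y) = 1 - 2 * sum(min(x_i, y_i)) / (sum(x_i) + sum(y_i)), computed
#' over the abundance columns. Pairs of all-zero samples, for which the
#' formula is undefined, are reported as 0 with a warning.
#'
#' @param abund non-negative abundance matrix (vOTUs x samples), e.g. TPM
#'   from [compute_tpm()].
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(abund) {
  stopifnot(is.matrix(abund), all(abund >= 0), ncol(abund) >= 2)
  d <- as.matrix(vegan::vegdist(t(abund), method = "bray"))
  if (anyNA(d)) {
    warning("all-zero sample pair(s): Bray-Curtis undefined, reported as 0")
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Global NMDS minimizing Kruskal stress-1 by iterative monotone (isotonic)
#' regression, run from `n_restarts` starting configurations (first start
#' metric; remaining random) with the lowest-stress solution returned. The
#' configuration fit is delegated to [vegan::monoMDS()].
#'
#' @param d square symmetric dissimilarity matrix with zero diagonal.
#' @param k number of ordination dimensions.
#' @param n_restarts number of starting configurations.
#' @param max_iter maximum iterations per start.
#' @param tol stress ratio convergence tolerance.
#' @param seed integer seed for the random starts.
#' @return list of class `nmds_result`: `points` (n x k coordinates),
#'   `stress` (Kruskal stress-1, fraction), `converged`, `n_restarts`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 300, tol = 1e-6,
                 seed = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isSymmetric(unname(d), tol = 1e-8)) {
    stop("d must be a square symmetric dissimilarity matrix")
  }
  if (any(diag(d) != 0)) stop("d must have a zero diagonal")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(d)
  if (n <= 2) {
    # two points are always perfectly representable
    pts <- matrix(0, n, k, dimnames = list(rownames(d), NULL))
    if (n == 2) pts[2, 1] <- d[1, 2]
    return(structure(list(points = pts, stress = 0, converged = TRUE,
                          n_restarts = 0L), class = "nmds_result"))
  }
  dd <- stats::as.dist(d)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- if (r == 1) {
      y <- suppressWarnings(stats::cmdscale(dd, k = k))
      if (ncol(y) < k) y <- cbind(y, matrix(0, n, k - ncol(y)))
      y
    } else {
      matrix(stats::runif(n * k, -1, 1), n, k)
    }
    fit <- vegan::monoMDS(dd, y = init, k = k, model = "global",
                          maxit = max_iter, sratmax = 1 - tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  structure(list(
    points = `rownames<-`(best$points, rownames(d)),
    stress = best$stress,
    converged = best$icause %in% c(2L, 3L),
    n_restarts = as.integer(n_restarts)
  ), class = "nmds_result")
}

#' Permutational multivariate ANOVA (PERMANOVA) on a dissimilarity matrix
#'
#' One-way PERMANOVA: partitions the total sum of squared dissimilarities
#' into among- and within-group components computed directly on the
#' dissimilarity matrix, forms the pseudo-F statistic
#' F = (SS_A / (a - 1)) / (SS_W / (N - a)), and obtains its permutation
#' p-value by uniformly permuting the group labels:
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations).
#'
#' @param d square symmetric dissimilarity matrix.
#' @param labels group label per sample (>= 2 groups).
#' @param n_permutations number of label permutations.
#' @param seed integer seed.
#' @return list of class `permanova_result`: `F`, `R2`, `p_value`,
#'   `n_permutations`, `ss_among`, `ss_within`, `ss_total`.
#' @export
permanova <- function(d, labels, n_permutations = 999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(length(labels) == n, n_permutations >= 1)
  labels <- as.character(labels)
  a <- length(unique(labels))
  if (a < 2) stop("labels must define at least 2 groups")
  if (n - a < 1) stop("no residual degrees of freedom: need N > #groups")
  if (!is.null(seed)) set.seed(seed)
  d2 <- d^2
  ss_total <- sum(d2) / (2 * n)
  ss_within <- function(lab) {
    s <- 0
    for (g in unique(lab)) {
      i <- which(lab == g)
      s <- s + sum(d2[i, i]) / (2 * length(i))
    }
    s
  }
  f_stat <- function(lab) {
    ssw <- ss_within(lab)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(labels)
  hits <- 0L
  for (p in seq_len(n_permutations)) {
    if (f_stat(labels[sample.int(n)]) >= f_obs) hits <- hits + 1L
  }
  ssw_obs <- ss_within(labels)
  structure(list(
    F = f_obs,
    R2 = (ss_total - ssw_obs) / ss_total,
    p_value = (1 + hits) / (1 + n_permutations),
    n_permutations = as.integer(n_permutations),
    ss_among = ss_total - ssw_obs,
    ss_within = ssw_obs,
    ss_total = ss_total
  ), class = "permanova_result")
}
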