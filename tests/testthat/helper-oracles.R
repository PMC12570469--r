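# independent oracles and fixture builders shared across test files

# all n! orderings of 1..n as rows (n small)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# brute-force two-sided Mann-Whitney p by enumerating all C(n1+n2, n1)
# assignments of the pooled observations to group 1
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(length(pooled), n1), 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# random logical occurrence matrix with dimnames
random_occ <- function(n_votu, samples, p = 0.4, seed = 1) {
  set.seed(seed)
  matrix(runif(n_votu * length(samples)) < p, n_votu, length(samples),
         dimnames = list(sprintf("v%03d", seq_len(n_votu)), samples))
}

# minimal design over explicit labels
mini_design <- function(sample_id, phenotype, compartment) {
  data.frame(sample_id = sample_id, phenotype = phenotype,
             compartment = compartment, replicate = seq_along(sample_id),
             stringsAsFactors = FALSE)
}

small_coverage <- function() {
  data.frame(
    votu_id = c("a", "a", "b", "b"),
    sample_id = c("s1", "s2", "s1", "s2"),
    contig_length = c(1000L, 1000L, 2000L, 2000L),
    covered_bases = c(750L, 749L, 2000L, 100L),
    mapped_reads = c(10L, 5L, 10L, 0L),
    stringsAsFactors = FALSE
  )
}
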