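test_that("minimum-length filter is inclusive at the boundary", {
  cat <- data.frame(seq_id = c("a", "b", "c"),
                    length = c(4999, 5000, 5001))
  expect_equal(filter_min_length(cat)$seq_id, c("b", "c"))
  expect_equal(nrow(filter_min_length(cat[0, ])), 0)

  set.seed(8)
  cat2 <- data.frame(seq_id = sprintf("s%03d", 1:100),
                     length = sample(3000:8000, 100))
  expect_identical(filter_min_length(cat2)$seq_id,
                   cat2$seq_id[cat2$length >= 5000])
  expect_error(filter_min_length(data.frame(length = c(10, -1))), "positive")
})

test_that("greedy longest-first dereplication follows the hand-run rule", {
  cat <- data.frame(seq_id = c("A", "B", "C"), length = c(9000, 8000, 7000))
  # chain: A-B and B-C qualify, A-C does not -> {A, B}, {C}
  pairs <- data.frame(seq_a = c("A", "B"), seq_b = c("B", "C"),
                      identity = c(0.97, 0.98), coverage = c(0.9, 0.85))
  res <- dereplicate(cat, pairs)
  expect_equal(res$representative[res$seq_id == "B"], "A")
  expect_equal(res$representative[res$seq_id == "C"], "C")
  expect_equal(sum(res$is_representative), 2)

  # no qualifying pairs: every sequence its own cluster
  weak <- transform(pairs, identity = 0.90)
  expect_true(all(dereplicate(cat, weak)$is_representative))
  expect_true(all(dereplicate(cat, pairs[0, ])$is_representative))

  # all-vs-all qualifying: single cluster, longest is representative
  full <- data.frame(seq_a = c("A", "A", "B"), seq_b = c("B", "C", "C"),
                     identity = 0.99, coverage = 0.95)
  res2 <- dereplicate(cat, full)
  expect_true(all(res2$representative == "A"))

  expect_error(dereplicate(cat, data.frame(seq_a = "A", seq_b = "Z",
                                           identity = 1, coverage = 1)),
               "unknown")
})

test_that("dereplication partitions the catalog and members match their representative", {
  set.seed(13)
  n <- 30
  cat <- data.frame(seq_id = sprintf("q%02d", 1:n),
                    length = sample(5000:50000, n))
  combos <- t(utils::combn(cat$seq_id, 2))
  pairs <- data.frame(seq_a = combos[, 1], seq_b = combos[, 2],
                      identity = runif(nrow(combos), 0.9, 1),
                      coverage = runif(nrow(combos), 0.6, 1))
  res <- dereplicate(cat, pairs)
  # partition: every sequence in exactly one cluster
  expect_setequal(res$seq_id, cat$seq_id)
  expect_true(all(res$representative %in% res$seq_id[res$is_representative]))
  # representative is the longest member of its cluster
  for (cl in unique(res$cluster)) {
    mem <- res[res$cluster == cl, ]
    expect_equal(mem$representative[1],
                 mem$seq_id[which.max(mem$length)])
  }
  # every non-representative member qualifies against its representative
  key <- c(paste(pairs$seq_a, pairs$seq_b)[pairs$identity >= 0.95 &
                                             pairs$coverage >= 0.80],
           paste(pairs$seq_b, pairs$seq_a)[pairs$identity >= 0.95 &
                                             pairs$coverage >= 0.80])
  nonrep <- res[!res$is_representative, ]
  expect_true(all(paste(nonrep$seq_id, nonrep$representative) %in% key))
})

test_that("presence calling is inclusive at 75% breadth and matches a row scan", {
  cov <- small_coverage()
  occ <- call_presence(cov)
  expect_true(occ["a", "s1"])    # 750/1000 exactly at threshold
  expect_false(occ["a", "s2"])   # 749/1000 just below
  expect_true(occ["b", "s1"])
  expect_false(occ["b", "s2"])

  set.seed(4)
  n <- 200
  rcov <- data.frame(
    votu_id = sample(sprintf("v%02d", 1:20), n, replace = TRUE),
    sample_id = sample(sprintf("s%02d", 1:10), n, replace = TRUE),
    contig_length = sample(5000:20000, n),
    stringsAsFactors = FALSE
  )
  rcov <- rcov[!duplicated(rcov[, 1:2]), ]
  rcov$covered_bases <- floor(runif(nrow(rcov)) * rcov$contig_length)
  rcov$mapped_reads <- rpois(nrow(rcov), 20)
  occ2 <- call_presence(rcov)
  for (r in seq_len(nrow(rcov))) {
    expect_identical(unname(occ2[rcov$votu_id[r], rcov$sample_id[r]]),
                     rcov$covered_bases[r] / rcov$contig_length[r] >= 0.75)
  }
  # missing pairs are absent
  expect_equal(sum(occ2), sum(rcov$covered_bases / rcov$contig_length >= 0.75))

  expect_error(call_presence(transform(cov, contig_length = 0)), "positive")
})

test_that("raising the breadth threshold never adds a presence", {
  set.seed(5)
  cov <- data.frame(
    votu_id = rep(sprintf("v%02d", 1:15), each = 6),
    sample_id = rep(sprintf("s%d", 1:6), 15),
    contig_length = 10000L,
    covered_bases = sample(0:10000, 90, replace = TRUE),
    mapped_reads = 1L
  )
  prev <- call_presence(cov, 0.5)
  for (thr in c(0.6, 0.75, 0.9, 1)) {
    cur <- call_presence(cov, thr)
    expect_true(all(prev | !cur))  # cur implies prev
    prev <- cur
  }
})

test_that("TPM normalizes length-corrected rates to a million per sample", {
  solo <- data.frame(votu_id = "a", sample_id = "s1", contig_length = 8000L,
                     covered_bases = 8000L, mapped_reads = 3L)
  expect_equal(unname(compute_tpm(solo)["a", "s1"]), 1e6)

  # equal reads on lengths L and 2L: 2/3 vs 1/3 of a million
  two <- data.frame(votu_id = c("a", "b"), sample_id = "s1",
                    contig_length = c(5000L, 10000L),
                    covered_bases = c(5000L, 10000L),
                    mapped_reads = c(10L, 10L))
  tpm <- compute_tpm(two)
  expect_equal(unname(tpm["a", "s1"]), 2e6 / 3, tolerance = 1e-9)
  expect_equal(unname(tpm["b", "s1"]), 1e6 / 3, tolerance = 1e-9)

  d <- generate_design(2)
  sim <- generate_coverage(d, sim_params(n_votus = 60, seed = 6))
  full <- compute_tpm(sim$coverage)
  sums <- colSums(full)
  expect_true(all(abs(sums - 1e6) < 1e-6 * 1e6 | sums == 0))

  # scale invariance: multiplying a sample's reads by a constant
  scaled <- transform(sim$coverage, mapped_reads = mapped_reads * 7L)
  expect_equal(compute_tpm(scaled), full, tolerance = 1e-12)
})

test_that("mask_absent zeroes sub-threshold vOTUs before normalization", {
  cov <- data.frame(votu_id = c("present", "absent"), sample_id = "s1",
                    contig_length = c(1000L, 1000L),
                    covered_bases = c(900L, 300L),
                    mapped_reads = c(5L, 50L))
  masked <- compute_tpm(cov, mask_absent = TRUE)
  expect_equal(unname(masked["present", "s1"]), 1e6)
  expect_equal(unname(masked["absent", "s1"]), 0)
  unmasked <- compute_tpm(cov)
  expect_true(unmasked["absent", "s1"] > 0)
  expect_equal(sum(unmasked[, "s1"]), 1e6)
})

test_that("depth files round-trip through the samtools dialect", {
  lengths <- data.frame(votu_id = c("c1", "c2"), length = c(10L, 20L))
  f <- withr::local_tempfile(fileext = ".tsv")

  # 7 of 10 positions covered -> breadth 0.7; c2 fully covered
  write_depth_file(list(c1 = c(1, 1, 2, 0, 0, 3, 1, 1, 1, 0),
                        c2 = rep(2L, 20)), f)
  cov <- read_depth_file(f, lengths, sample_id = "sA", read_length = 10)
  expect_equal(cov$covered_bases[cov$votu_id == "c1"], 7L)
  expect_equal(cov$covered_bases[cov$votu_id == "c2"], 20L)
  expect_equal(cov$covered_bases / cov$contig_length, c(0.7, 1.0))
  expect_equal(cov$mapped_reads, c(round(11 / 10), round(40 / 10)))
  expect_true(all(cov$sample_id == "sA"))

  # synthetic random profile round-trip
  set.seed(3)
  prof <- list(c1 = sample(0:4, 10, replace = TRUE),
               c2 = sample(0:2, 20, replace = TRUE))
  write_depth_file(prof, f)
  cov2 <- read_depth_file(f, lengths, "sB")
  expect_equal(cov2$covered_bases, vapply(prof, function(p) sum(p >= 1), 1L),
               ignore_attr = TRUE)

  # malformed line reported with its number
  writeLines(c("c1\t1\t3", "c1\ttwo\t4"), f)
  expect_error(read_depth_file(f, lengths, "sC"), "line 2")
  writeLines(c("c1\t1\t3", "c1\t99\t4"), f)
  expect_error(read_depth_file(f, lengths, "sC"), "exceeds contig length")
})

test_that("matrix CSVs round-trip losslessly", {
  occ <- random_occ(12, sprintf("s%d", 1:5), seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_occurrence_csv(occ, f)
  expect_identical(read_occurrence_csv(f), occ)

  tpm <- matrix(runif(20) * 1e5, 4, 5,
                dimnames = list(letters[1:4], sprintf("s%d", 1:5)))
  write_abundance_csv(tpm, f)
  expect_equal(read_abundance_csv(f), tpm, tolerance = 1e-6)
})
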