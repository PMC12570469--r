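test_that("multi-sample filter keeps exactly the rows with >= 2 presences", {
  occ <- matrix(FALSE, 3, 3, dimnames = list(c("a", "b", "c"),
                                             c("s1", "s2", "s3")))
  occ["a", "s1"] <- TRUE                 # singleton: excluded
  occ["b", c("s1", "s2")] <- TRUE        # two samples: included
  m <- multi_sample_filter(occ)
  expect_equal(rownames(m), "b")

  r <- random_occ(50, sprintf("s%d", 1:6), seed = 14)
  expect_identical(multi_sample_filter(r), r[rowSums(r) >= 2, , drop = FALSE])
})

test_that("sharing classes partition the multi-sample set", {
  d <- mini_design(
    c("s1", "s2", "s3", "s4", "s5", "s6"),
    rep(c("short", "tall"), each = 3),
    rep(c("bulk", "rhizosphere", "root"), 2))
  occ <- matrix(FALSE, 4, 6, dimnames = list(c("a", "b", "c", "e"),
                                             d$sample_id))
  occ["a", c("s1", "s2")] <- TRUE       # two short samples -> short-only
  occ["b", c("s1", "s4")] <- TRUE       # short + tall -> both
  occ["c", c("s2", "s6")] <- TRUE       # rhizosphere + root
  occ["e", c("s1", "s2", "s6")] <- TRUE # all three compartments

  ph <- classify_phenotype_sharing(occ, d)
  expect_equal(unname(ph$classes[c("a", "b")]),
               c("short-only", "both-phenotypes"))
  cp <- classify_compartment_sharing(occ, d)
  expect_equal(unname(cp$classes[c("c", "e")]),
               c("rhizosphere+root", "all-three"))
  expect_equal(sum(ph$counts), ph$n_multi)
  expect_equal(sum(cp$counts), cp$n_multi)

  # brute-force set computation on a random matrix
  occ2 <- multi_sample_filter(random_occ(60, d$sample_id, seed = 15))
  cp2 <- classify_compartment_sharing(occ2, d)
  for (v in rownames(occ2)) {
    comps <- sort(unique(d$compartment[match(colnames(occ2)[occ2[v, ]],
                                             d$sample_id)]))
    expected <- switch(paste(comps, collapse = ","),
      "bulk" = "bulk-only", "rhizosphere" = "rhizosphere-only",
      "root" = "root-only", "bulk,rhizosphere" = "bulk+rhizosphere",
      "rhizosphere,root" = "rhizosphere+root", "bulk,root" = "bulk+root",
      "bulk,rhizosphere,root" = "all-three")
    expect_equal(unname(cp2$classes[v]), expected)
  }
  expect_equal(sum(cp2$counts), nrow(occ2))
})

test_that("null model conserves richness and matches the closed form", {
  # degenerate case: richness equals catalog size, so every replicate is
  # the saturated matrix and the expected classes equal the observed ones
  d2 <- mini_design(c("s1", "s2"), c("short", "tall"), c("bulk", "bulk"))
  sat <- matrix(TRUE, 3, 2, dimnames = list(c("a", "b", "c"), d2$sample_id))
  nm_sat <- null_model(sat, d2, "phenotype", n_replicates = 50, seed = 1)
  expect_equal(unname(nm_sat$expected_counts["both-phenotypes"]), 3)
  expect_true(all(nm_sat$replicate_n_multi == 3))

  # 2 samples, catalog 3, richness 1 each: P(shared vOTU) = 1/3
  occ <- matrix(FALSE, 3, 2, dimnames = list(c("a", "b", "c"), d2$sample_id))
  occ["a", "s1"] <- TRUE; occ["b", "s2"] <- TRUE
  nm <- null_model(occ, d2, "phenotype", n_replicates = 10000, seed = 2)
  p_hat <- mean(nm$replicate_counts[, "both-phenotypes"])
  se <- sqrt((1 / 3) * (2 / 3) / 10000)
  expect_lt(abs(p_hat - 1 / 3), 3 * se)
})

test_that("Monte-Carlo null expectations converge to exhaustive enumeration", {
  d <- mini_design(c("s1", "s2", "s3"),
                   c("short", "tall", "short"),
                   c("bulk", "rhizosphere", "root"))
  occ <- matrix(FALSE, 3, 3, dimnames = list(c("a", "b", "c"), d$sample_id))
  occ[1, 1] <- TRUE; occ[2, 2] <- TRUE; occ[c(1, 3), 3] <- TRUE  # rich 1,1,2

  ex_ph <- exact_null_expectations(c(s1 = 1, s2 = 1, s3 = 2), 3, d, "phenotype")
  ex_cp <- exact_null_expectations(c(s1 = 1, s2 = 1, s3 = 2), 3, d, "compartment")
  expect_equal(ex_ph$n_combinations, 3 * 3 * 3)

  for (cls in list(c("phenotype", "ph"), c("compartment", "cp"))) {
    nm <- null_model(occ, d, cls[1], n_replicates = 10000, seed = 3)
    ex <- if (cls[1] == "phenotype") ex_ph else ex_cp
    se <- apply(nm$replicate_counts, 2, sd) / sqrt(10000)
    expect_true(all(abs(nm$expected_counts - ex$expected_counts)
                    <= 3 * se + 1e-9))
  }
})

test_that("exact enumeration handles closed-form, guard and degenerate cases", {
  d2 <- mini_design(c("s1", "s2"), c("short", "tall"), c("bulk", "bulk"))
  ex <- exact_null_expectations(c(s1 = 1, s2 = 1), 3, d2, "phenotype")
  expect_equal(unname(ex$expected_counts["both-phenotypes"]), 1 / 3)
  expect_equal(ex$expected_n_multi, 1 / 3)

  # single sample: the multi-sample set is always empty
  d1 <- mini_design("s1", "short", "bulk")
  ex1 <- exact_null_expectations(c(s1 = 2), 4, d1, "phenotype")
  expect_equal(ex1$expected_n_multi, 0)
  expect_true(all(is.na(ex1$expected_proportions)))

  # symmetric design: proportions symmetric under phenotype swap
  d4 <- mini_design(c("s1", "s2", "s3", "s4"),
                    c("short", "short", "tall", "tall"),
                    rep("bulk", 4))
  exs <- exact_null_expectations(c(s1 = 1, s2 = 1, s3 = 1, s4 = 1), 3, d4,
                                 "phenotype")
  expect_equal(unname(exs$expected_counts["short-only"]),
               unname(exs$expected_counts["tall-only"]))

  expect_error(exact_null_expectations(setNames(rep(10, 6), paste0("s", 1:6)),
                                       30, generate_design(1), "phenotype"),
               "too large")
})

test_that("chi-squared goodness-of-fit matches hand computation", {
  # observed exactly proportional to expected
  even <- chi_square_gof(c(10, 20, 30), c(1, 2, 3) / 6)
  expect_equal(even$chi2, 0)
  expect_equal(even$p_value, 1)

  suppressWarnings({
    hand <- chi_square_gof(c(10, 20, 30), rep(1 / 3, 3))
  })
  expect_equal(hand$chi2, 10)     # (10-20)^2/20 + 0 + (30-20)^2/20
  expect_equal(hand$df, 2L)
  expect_equal(hand$p_value, pchisq(10, 2, lower.tail = FALSE))
  # cross-check against stats::chisq.test
  ct <- stats::chisq.test(c(10, 20, 30), p = rep(1 / 3, 3))
  expect_equal(hand$chi2, unname(ct$statistic))
  expect_equal(hand$p_value, ct$p.value)

  # structural zeros drop from df; impossible observation flagged infinite
  z <- chi_square_gof(c(30, 30, 0), c(0.5, 0.5, 0))
  expect_equal(z$df, 1L)
  inf <- chi_square_gof(c(30, 30, 5), c(0.5, 0.5, 0))
  expect_true(inf$infinite)
  expect_equal(inf$p_value, 0)

  expect_error(chi_square_gof(c(0, 0), c(0.5, 0.5)), "sum to > 0")
  expect_error(chi_square_gof(c(1, 1), c(0.5, 0.4)), "sum to 1")
  expect_warning(chi_square_gof(c(3, 5), c(0.5, 0.5)), "below 5")
})

test_that("per-cell null mode conserves cell-level incidence counts", {
  d <- generate_design(2)
  occ <- random_occ(40, d$sample_id, p = 0.3, seed = 16)
  nm <- null_model(occ, d, "compartment", n_replicates = 30,
                   mode = "per_cell", seed = 4)
  expect_s3_class(nm, "null_model_result")
  expect_equal(sum(nm$observed),
               nrow(multi_sample_filter(occ)))
  expect_true(all(nm$replicate_n_multi >= 0))
})
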