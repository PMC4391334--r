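test_that("build_fingerprint extracts calls in locus order", {
  calls <- genotype_calls(matrix(c("CC", "CD", "DD", NA), 2, 2,
                                 dimnames = list(c("cgA", "cgB"),
                                                 c("s1", "s2"))))
  fp <- build_fingerprint(calls, "s1", c("cgB", "cgA"))
  expect_identical(fp$calls, c("CD", "CC"))
  expect_error(build_fingerprint(calls, "s9", "cgA"), "unknown sample")
  expect_error(build_fingerprint(calls, "s1", c("cgA", "cgZ")), "cgZ")
  expect_warning(empty <- build_fingerprint(calls, "s1", character()),
                 "empty")
  expect_length(empty$calls, 0)
})

test_that("concordance is symmetric, self-identical, and counts only joint calls", {
  calls <- toy_calls(100, 2, seed = 21)
  a <- build_fingerprint(calls, "s01", rownames(calls))
  b <- build_fingerprint(calls, "s02", rownames(calls))
  ab <- concordance(a, b)
  ba <- concordance(b, a)
  expect_equal(ab$concordance, ba$concordance)
  expect_equal(ab$n_compared, sum(!is.na(calls[, 1]) & !is.na(calls[, 2])))
  self <- concordance(a, a)
  expect_equal(self$concordance, 1)
  expect_equal(self$n_compared, sum(!is.na(a$calls)))

  # 5 discordant loci out of 100 fully-called
  m <- matrix("CC", 100, 2, dimnames = list(sprintf("p%03d", 1:100),
                                            c("x", "y")))
  m[1:5, 2] <- "DD"
  g <- genotype_calls(m)
  expect_equal(concordance(build_fingerprint(g, "x", rownames(g)),
                           build_fingerprint(g, "y", rownames(g)))$concordance,
               0.95)

  all_na <- genotype_calls(matrix(NA_character_, 2, 2,
                                  dimnames = list(c("a", "b"), c("x", "y"))))
  expect_error(concordance(build_fingerprint(all_na, "x", c("a", "b")),
                           build_fingerprint(all_na, "y", c("a", "b"))),
               "insufficient overlap")
})

test_that("random match probability follows the HWE product rule", {
  g <- genotype_calls(matrix(c("CD", "CC", "DD", NA), 4, 1,
                             dimnames = list(paste0("L", 1:4), "s")))
  f <- c(L1 = 0.5, L2 = 0.5, L3 = 0.5, L4 = 0.5)
  one <- random_match_probability(build_fingerprint(g, "s", "L1"), f)
  expect_equal(as.numeric(one), log10(0.5))
  two <- random_match_probability(build_fingerprint(g, "s", c("L2", "L3")), f)
  expect_equal(as.numeric(two), log10(0.25 * 0.25))
  # missing locus skipped and counted
  four <- random_match_probability(build_fingerprint(g, "s", paste0("L", 1:4)), f)
  expect_identical(attr(four, "n_used"), 3L)
  expect_identical(attr(four, "n_missing_skipped"), 1L)
  expect_error(random_match_probability(build_fingerprint(g, "s", "L1"),
                                        c(L1 = 0)), "degenerate")
  expect_error(random_match_probability(build_fingerprint(g, "s", "L1"),
                                        c(LX = 0.2)), "L1")
})

test_that("random match probability is non-increasing as loci are added", {
  set.seed(407)
  calls <- toy_calls(200, 1, seed = 33)
  freqs <- setNames(runif(200, 0.05, 0.5), rownames(calls))
  prev <- 0
  for (k in c(10, 50, 100, 200)) {
    fp <- build_fingerprint(calls, colnames(calls)[1], rownames(calls)[1:k])
    cur <- as.numeric(random_match_probability(fp, freqs))
    expect_lte(cur, prev)
    prev <- cur
  }
  # analytic bound: every genotype frequency >= 0.25 when f_D = 0.5 and CD
  g <- genotype_calls(matrix("CD", 1000, 1,
                             dimnames = list(sprintf("m%04d", 1:1000), "s")))
  f <- setNames(rep(0.5, 1000), rownames(g))
  v <- random_match_probability(build_fingerprint(g, "s", rownames(g)), f)
  expect_gte(as.numeric(v), 1000 * log10(0.25))
})

test_that("match_samples ranks the true individual first", {
  sim <- simulate_dataset(simulation_config(n_snp_probes = 200,
                                            n_background_probes = 0,
                                            maf_range = c(0.1, 0.5),
                                            n_samples = 10, seed = 99))
  g <- call_genotypes(sim$beta, rownames(sim$truth$genotypes))
  res <- match_samples(g, g, min_overlap = 30)
  top <- res[!duplicated(res$query), ]
  expect_identical(top$reference[match(colnames(g), top$query)], colnames(g))
  expect_true(all(top$concordance == 1))
  # unrelated individuals never approach a perfect match
  cross <- res[res$query != res$reference, ]
  expect_lt(max(cross$concordance), 0.9)
})

test_that("match_samples honours min_overlap and disjoint loci error", {
  calls <- toy_calls(10, 3, seed = 5)
  expect_warning(res <- match_samples(calls, calls, min_overlap = 1000),
                 "omitted")
  expect_identical(nrow(res), 0L)
  other <- genotype_calls(matrix("CC", 2, 2,
                                 dimnames = list(c("zz1", "zz2"),
                                                 c("a", "b"))))
  expect_error(match_samples(calls, other), "no loci")
})

test_that("redaction removes listed probes, reports absentees, idempotent", {
  set.seed(408)
  m <- random_beta_matrix(30, 8)
  red <- redact_probes(m, c(rownames(m)[1:10], "ghost"))
  expect_identical(nrow(red$matrix), 20L)
  expect_identical(red$n_removed, 10L)
  expect_identical(red$absent, "ghost")
  expect_identical(colnames(red$matrix), colnames(m))
  again <- redact_probes(red$matrix, rownames(m)[1:10])
  expect_identical(again$n_removed, 0L)
  expect_identical(unclass(again$matrix), unclass(red$matrix))
  none <- redact_probes(m, character())
  expect_identical(unclass(none$matrix), unclass(m))

  # redaction then re-audit never returns a redacted probe
  sim <- simulate_dataset(simulation_config(n_snp_probes = 50,
                                            n_background_probes = 200,
                                            seed = 77))
  sel <- select_informative_probes(sim$beta)
  redacted <- redact_probes(sim$beta, sel$probe_id)$matrix
  resel <- select_informative_probes(redacted)
  expect_length(intersect(resel$probe_id, sel$probe_id), 0)
})
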