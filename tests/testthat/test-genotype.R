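test_that("assign_bin follows the strict tri-modal inequalities", {
  expect_identical(assign_bin(c(0.85, 0.50, 0.10, 0.28, NA)),
                   c("X", "Y", "Z", "unbinned", "missing"))
  # exact boundary values are deliberately unbinned
  expect_identical(assign_bin(c(0.7, 0.3, 0.25)),
                   rep("unbinned", 3))
  expect_error(assign_bin(1.2), "outside")
  expect_error(assign_bin(-0.1), "outside")
})

test_that("binning is a partition: exactly one label per value", {
  set.seed(401)
  beta <- c(runif(500), 0, 1, 0.25, 0.3, 0.7, NA)
  bins <- assign_bin(beta)
  expect_true(all(bins %in% c("X", "Y", "Z", "unbinned", "missing")))
  expect_identical(bins, vapply(beta, assign_bin_oracle, ""))
})

test_that("bin_profile counts every sample exactly once", {
  p <- bin_profile(c(0.9, 0.5, 0.1, NA))
  expect_identical(unclass(p)[c("n_x", "n_y", "n_z", "n_unbinned", "n_missing")],
                   c(n_x = 1L, n_y = 1L, n_z = 1L, n_unbinned = 0L,
                     n_missing = 1L))
  expect_identical(sum(bin_profile(rep(0.99, 10))), 10L)
  row <- c(rep(0.9, 60), rep(0.5, 40), rep(0.05, 11))
  expect_identical(unname(unclass(bin_profile(row))), c(60L, 40L, 11L, 0L, 0L))
  expect_error(bin_profile(numeric()), "empty")
})

test_that("candidacy rules use the ceil-based binned-count threshold", {
  prof <- function(x, y, z, u = 0L, m = 0L)
    structure(c(n_x = x, n_y = y, n_z = z, n_unbinned = u, n_missing = m),
              class = "bin_profile")
  expect_true(passes_candidacy(prof(60L, 40L, 11L), 111))
  r <- passes_candidacy(prof(100L, 5L, 3L, 3L), 111)
  expect_false(as.logical(r))
  expect_identical(attr(r, "reason"), "homozygote_Z")
  # 105 binned < ceiling(0.95 * 111) = 106
  r2 <- passes_candidacy(prof(99L, 0L, 6L, 6L), 111)
  expect_false(as.logical(r2))
  expect_identical(attr(r2, "reason"), "binned_fraction")
  r3 <- passes_candidacy(prof(3L, 100L, 5L, 3L), 111)
  expect_identical(attr(r3, "reason"), "homozygote_X")
})

test_that("call_genotypes maps bins to calls and tolerates subsets", {
  m <- beta_matrix(matrix(c(0.95, 0.5, 0.02, 0.27, NA, 0.8), 3, 2,
                          dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
  g <- call_genotypes(m)
  expect_identical(unname(g[, "s1"]), c("CC", "CD", "DD"))
  expect_true(is.na(g["a", "s2"]))  # 0.27 is unbinned -> missing call
  expect_true(is.na(g["b", "s2"]))
  expect_identical(dim(call_genotypes(m, character())), c(0L, 2L))
  expect_error(call_genotypes(m, "nope"), "nope")
})

test_that("select_informative_probes agrees with the brute-force oracle", {
  set.seed(402)
  for (rep in 1:25) {
    m <- random_beta_matrix(sample(3:20, 1), sample(5:20, 1))
    params <- candidacy_params(min_binned_fraction = 0.6,
                               min_homozygote_count = 1L, hwe_p_min = 0.01)
    got <- select_informative_probes(m, params)
    want <- select_probes_oracle(unclass(m), 0.6, 1, 0.01)
    expect_identical(got$probe_id, want$probe_id)
    expect_equal(got$maf, want$maf)
    expect_equal(got$het_obs, want$het_obs)
    expect_identical(got$n_cd, want$n_cd)
  }
})

test_that("constant matrices yield an empty selection", {
  m <- beta_matrix(matrix(0.8, 5, 10,
                          dimnames = list(paste0("p", 1:5), paste0("s", 1:10))))
  expect_identical(nrow(select_informative_probes(m)), 0L)
})

test_that("tightening any filter never enlarges the selected set", {
  set.seed(403)
  m <- random_beta_matrix(40, 15, na_rate = 0.02)
  base <- candidacy_params(min_binned_fraction = 0.6,
                           min_homozygote_count = 1L, hwe_p_min = 0.01)
  sel0 <- select_informative_probes(m, base)$probe_id
  for (p in list(candidacy_params(0.6, 2L, 0.01),
                 candidacy_params(0.6, 1L, 0.2),
                 candidacy_params(0.8, 1L, 0.01),
                 candidacy_params(0.8, 3L, 0.3))) {
    expect_true(all(select_informative_probes(m, p)$probe_id %in% sel0))
  }
})

test_that("selection recovers planted SNP probes and rejects background", {
  # sensitivity is checked against its exact binomial prediction for this
  # world: a probe passes iff >=4 of each homozygote class is drawn, so
  # P(select | maf) = P(Bin(n, maf^2) >= 4) * P(Bin(n, (1-maf)^2) >= 4),
  # times HWE-screen survival (~0.99)
  set.seed(404)
  n_sel <- n_planted <- pred <- pred_var <- 0
  fp <- bg <- 0
  hi_sel <- hi_tot <- 0
  for (seed in 1:5) {
    sim <- simulate_dataset(simulation_config(n_snp_probes = 200,
                                              n_background_probes = 1000,
                                              seed = 500 + seed))
    sel <- select_informative_probes(sim$beta)
    truth <- sim$truth$probes
    snp <- truth[truth$class == "snp", ]
    is_sel <- snp$probe_id %in% sel$probe_id
    n_sel <- n_sel + sum(is_sel); n_planted <- n_planted + nrow(snp)
    pp <- 0.99 * pbinom(3, 111, snp$true_maf^2, lower.tail = FALSE) *
      pbinom(3, 111, (1 - snp$true_maf)^2, lower.tail = FALSE)
    pred <- pred + sum(pp); pred_var <- pred_var + sum(pp * (1 - pp))
    fp <- fp + sum(!grepl("^snp", sel$probe_id))
    bg <- bg + sum(truth$class == "background")
    hi <- snp$true_maf >= 0.3
    hi_sel <- hi_sel + sum(is_sel & hi); hi_tot <- hi_tot + sum(hi)
  }
  expect_lt(abs(n_sel - pred), 4 * sqrt(pred_var) + 1)
  expect_lte(fp / bg, 0.01)
  expect_gte(hi_sel / hi_tot, 0.95)
})

test_that("top_k respects ranking and ties", {
  s <- data.frame(probe_id = c("cgB", "cgA", "cgC"),
                  het_obs = c(0.6, 0.5, 0.5))
  s <- s[order(-s$het_obs, s$probe_id), ]
  expect_identical(top_k(s, 2)$probe_id, c("cgB", "cgA"))
  expect_identical(nrow(top_k(s, 99)), 3L)
  expect_error(top_k(s, 0), "positive")
})
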