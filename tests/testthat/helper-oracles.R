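# Independent oracles and fixture builders. Everything here is deliberately
# written the slow, literal way (scalar loops, direct arithmetic) so that it
# cannot share a bug with the vectorised implementation it checks.

# chi-square(1) upper tail via the normal distribution: P(X > c) = 2*P(Z > sqrt(c))
chisq1_tail_oracle <- function(chi2) 2 * pnorm(-sqrt(chi2))

# direct chi-square arithmetic on one count triple
hwe_oracle <- function(ncc, ncd, ndd) {
  n <- ncc + ncd + ndd
  fc <- (2 * ncc + ncd) / (2 * n)
  fd <- 1 - fc
  if (fc == 0 || fd == 0) return(list(chi2 = 0, p = 1))
  expected <- n * c(fc^2, 2 * fc * fd, fd^2)
  chi2 <- sum((c(ncc, ncd, ndd) - expected)^2 / expected)
  list(chi2 = chi2, p = chisq1_tail_oracle(chi2))
}

# literal scalar restatement of the three bin inequalities
assign_bin_oracle <- function(b) {
  if (is.na(b)) return("missing")
  if (b > 0.7) return("X")
  if (b > 0.3 && b < 0.7) return("Y")
  if (b < 0.25) return("Z")
  "unbinned"
}

# brute-force reimplementation of the whole discovery pipeline, scalar loops
# only: bin -> candidacy -> genotype counts -> HWE -> rank
select_probes_oracle <- function(m, min_binned_fraction = 0.95,
                                 min_homozygote_count = 4,
                                 hwe_p_min = 0.01) {
  n_samples <- ncol(m)
  rows <- list()
  for (p in rownames(m)) {
    nx <- ny <- nz <- 0L
    for (s in colnames(m)) {
      bin <- assign_bin_oracle(m[p, s])
      if (bin == "X") nx <- nx + 1L
      if (bin == "Y") ny <- ny + 1L
      if (bin == "Z") nz <- nz + 1L
    }
    if (nx + ny + nz < ceiling(min_binned_fraction * n_samples)) next
    if (nx < min_homozygote_count || nz < min_homozygote_count) next
    h <- hwe_oracle(nx, ny, nz)
    if (!(pchisq(h$chi2, 1, lower.tail = FALSE) > hwe_p_min)) next
    fc <- (2 * nx + ny) / (2 * (nx + ny + nz))
    rows[[p]] <- data.frame(probe_id = p, n_cc = nx, n_cd = ny, n_dd = nz,
                            maf = min(fc, 1 - fc),
                            het_obs = ny / (nx + ny + nz),
                            stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(probe_id = character(), n_cc = integer(),
                      n_cd = integer(), n_dd = integer(), maf = numeric(),
                      het_obs = numeric()))
  out <- do.call(rbind, rows)
  out <- out[order(-out$het_obs, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random beta matrix with a mix of tri-modal and arbitrary probes
random_beta_matrix <- function(n_probes, n_samples, na_rate = 0.05) {
  v <- matrix(NA_real_, n_probes, n_samples,
              dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                              sprintf("s%03d", seq_len(n_samples))))
  for (i in seq_len(n_probes)) {
    if (runif(1) < 0.5) {
      modes <- sample(c(0.95, 0.5, 0.05), n_samples, replace = TRUE)
      v[i, ] <- pmax(0, pmin(1, modes + rnorm(n_samples, 0, 0.05)))
    } else {
      v[i, ] <- runif(n_samples)
    }
  }
  v[matrix(runif(length(v)) < na_rate, n_probes)] <- NA
  beta_matrix(v)
}

# small deterministic call matrix for fingerprint/io tests
toy_calls <- function(n_probes = 5, n_samples = 4, seed = 11) {
  set.seed(seed)
  m <- matrix(sample(c("CC", "CD", "DD", NA), n_probes * n_samples,
                     replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1)),
              n_probes, n_samples,
              dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                              sprintf("s%02d", seq_len(n_samples))))
  genotype_calls(m)
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
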