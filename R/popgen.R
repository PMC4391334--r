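# Per-locus population genetics on two-allele genotype counts (C = the intact
# CpG cytosine, D = the unidentified non-C allele).

#' Genotype counts at one locus
#'
#' @param n_cc,n_cd,n_dd non-negative counts of the three genotype classes.
#' @return a `genotype_counts` list with an `n_total` field.
#' @export
genotype_counts <- function(n_cc, n_cd, n_dd) {
  n <- c(n_cc = n_cc, n_cd = n_cd, n_dd = n_dd)
  if (any(!is.finite(n)) || any(n < 0) || any(n != round(n)))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  structure(list(n_cc = as.integer(n[["n_cc"]]),
                 n_cd = as.integer(n[["n_cd"]]),
                 n_dd = as.integer(n[["n_dd"]]),
                 n_total = as.integer(sum(n))),
            class = "genotype_counts")
}

.as_counts <- function(counts) {
  if (inherits(counts, "genotype_counts")) return(counts)
  if (is.numeric(counts) && length(counts) == 3L)
    return(genotype_counts(counts[[1L]], counts[[2L]], counts[[3L]]))
  stop("expected genotype_counts or a numeric (n_cc, n_cd, n_dd) triple",
       call. = FALSE)
}

#' Allele frequencies from genotype counts
#'
#' `f_C = (2*n_cc + n_cd) / (2*n_total)` by allele counting; `f_D = 1 - f_C`.
#'
#' @param counts a [genotype_counts] object or `(n_cc, n_cd, n_dd)` vector.
#' @return named numeric vector `c(f_C=, f_D=)`.
#' @examples
#' allele_frequencies(c(81, 28, 2))   # f_D = 32/222
#' @export
allele_frequencies <- function(counts) {
  counts <- .as_counts(counts)
  if (counts$n_total < 1L)
    stop("allele frequencies are undefined for zero genotyped samples",
         call. = FALSE)
  f_c <- (2 * counts$n_cc + counts$n_cd) / (2 * counts$n_total)
  c(f_C = f_c, f_D = 1 - f_c)
}

#' Minor allele frequency
#'
#' @inheritParams allele_frequencies
#' @return the smaller of the two allele frequencies, in \[0, 0.5\].
#' @export
minor_allele_frequency <- function(counts) {
  unname(min(allele_frequencies(counts)))
}

#' Observed heterozygosity
#'
#' Fraction of genotyped individuals called heterozygous: `n_cd / n_total`.
#' This is the ranking statistic for "most informative" loci.
#'
#' @inheritParams allele_frequencies
#' @return numeric in \[0,1\].
#' @export
observed_heterozygosity <- function(counts) {
  counts <- .as_counts(counts)
  if (counts$n_total < 1L)
    stop("heterozygosity is undefined for zero genotyped samples",
         call. = FALSE)
  counts$n_cd / counts$n_total
}

#' Expected heterozygosity under HWE
#'
#' `2 * f_C * f_D`, at most 0.5.
#'
#' @inheritParams allele_frequencies
#' @return numeric in \[0, 0.5\].
#' @export
expected_heterozygosity <- function(counts) {
  f <- allele_frequencies(counts)
  unname(2 * f["f_C"] * f["f_D"])
}

# vectorised core shared by hwe_test() and select_informative_probes():
# Pearson chi-square, 1 df, no continuity correction, against expected
# (n*p^2, 2n*p*q, n*q^2). Monomorphic loci get chi2 = 0, p = 1 by convention.
hwe_test_vec <- function(n_cc, n_cd, n_dd) {
  n <- n_cc + n_cd + n_dd
  f_c <- (2 * n_cc + n_cd) / (2 * n)
  f_d <- 1 - f_c
  e_cc <- n * f_c^2
  e_cd <- 2 * n * f_c * f_d
  e_dd <- n * f_d^2
  mono <- f_c == 0 | f_d == 0
  chi2 <- ifelse(mono, 0,
                 (n_cc - e_cc)^2 / e_cc + (n_cd - e_cd)^2 / e_cd +
                   (n_dd - e_dd)^2 / e_dd)
  list(chi2 = unname(chi2),
       p = unname(ifelse(mono, 1, pchisq(chi2, df = 1, lower.tail = FALSE))),
       monomorphic = unname(mono))
}

#' Hardy-Weinberg equilibrium test
#'
#' Pearson chi-square goodness-of-fit with 1 degree of freedom and no
#' continuity correction, comparing observed genotype counts to the HWE
#' expectation computed from the sample allele frequencies. Monomorphic loci
#' are defined to pass (`chi2 = 0`, `p = 1`) and flagged — they carry no
#' genotype information and are removed by the homozygote-count candidacy rule
#' anyway.
#'
#' @inheritParams allele_frequencies
#' @return list with `chi2`, `p`, and logical `monomorphic`.
#' @examples
#' hwe_test(c(25, 50, 25))  # exact HWE proportions: chi2 = 0, p = 1
#' hwe_test(c(30, 40, 30))  # chi2 = 4, p ~ 0.0455
#' @export
hwe_test <- function(counts) {
  counts <- .as_counts(counts)
  if (counts$n_total < 1L)
    stop("HWE test is undefined for zero genotyped samples", call. = FALSE)
  hwe_test_vec(counts$n_cc, counts$n_cd, counts$n_dd)
}

#' Compare observed heterozygosity with a reference table
#'
#' Joins per-probe observed heterozygosity against an external reference
#' (e.g. heterozygosities listed by a genome browser for the SNP at each CpG)
#' and reports the Pearson correlation over shared probes. A high correlation
#' is evidence that the loci are genuine polymorphisms rather than epigenetic
#' variation. Probes absent from the reference are returned separately, never
#' dropped silently.
#'
#' @param summaries a `probe_summary` data.frame
#'   (from [select_informative_probes()]).
#' @param reference named numeric vector or two-column data.frame mapping
#'   probe IDs to reference heterozygosity.
#' @return list with `table` (probe_id, het_obs, het_ref, difference),
#'   `correlation` (Pearson, over shared probes), and `unmatched` (probe IDs
#'   missing from the reference).
#' @export
compare_heterozygosity <- function(summaries, reference) {
  if (is.data.frame(reference))
    reference <- setNames(as.numeric(reference[[2L]]),
                          as.character(reference[[1L]]))
  shared <- summaries$probe_id %in% names(reference)
  if (sum(shared) < 2L)
    stop("fewer than 2 probes shared with the reference table", call. = FALSE)
  tab <- data.frame(probe_id = summaries$probe_id[shared],
                    het_obs = summaries$het_obs[shared],
                    het_ref = unname(reference[summaries$probe_id[shared]]),
                    stringsAsFactors = FALSE)
  tab$difference <- tab$het_obs - tab$het_ref
  if (stats::sd(tab$het_ref) == 0 || stats::sd(tab$het_obs) == 0)
    stop("correlation undefined: heterozygosity column has no variance",
         call. = FALSE)
  list(table = tab,
       correlation = cor(tab$het_obs, tab$het_ref),
       unmatched = summaries$probe_id[!shared])
}
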