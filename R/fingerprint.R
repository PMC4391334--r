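# Genetic fingerprints and re-identification risk.
#
# A fingerprint is one sample's ordered genotype vector over a panel of
# informative loci. Two fingerprints from the same individual agree wherever
# both are called; two unrelated individuals agree only by chance, so
# concordance ranks candidate identities and the HWE product rule quantifies
# how surprising a full profile match would be.

#' Build a fingerprint for one sample
#'
#' @param calls a [genotype_calls] matrix.
#' @param sample_id one sample present in `calls`.
#' @param loci ordered probe IDs (unique, all present in `calls`); an empty
#'   panel yields a valid empty fingerprint with a warning.
#' @return a `fingerprint` list with `sample_id`, `loci`, `calls`.
#' @export
build_fingerprint <- function(calls, sample_id, loci) {
  if (!sample_id %in% colnames(calls))
    stop("unknown sample: ", sample_id, call. = FALSE)
  missing_loci <- setdiff(loci, rownames(calls))
  if (length(missing_loci))
    stop("locus not in call matrix: ",
         paste(head(missing_loci, 5L), collapse = ", "), call. = FALSE)
  if (anyDuplicated(loci))
    stop("fingerprint loci must be unique", call. = FALSE)
  if (length(loci) == 0L)
    warning("empty locus panel: fingerprint carries no information",
            call. = FALSE)
  structure(list(sample_id = sample_id,
                 loci = as.character(loci),
                 calls = unname(unclass(calls)[loci, sample_id])),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("fingerprint of '%s': %d loci (%d called)\n", x$sample_id,
              length(x$loci), sum(!is.na(x$calls))))
  invisible(x)
}

#' Concordance between two fingerprints
#'
#' Compares only loci present in both panels and non-missing in both calls.
#' Symmetric in its arguments.
#'
#' @param a,b `fingerprint` objects sharing at least one locus.
#' @return a `match_result` list: `n_compared`, `n_concordant`, `concordance`,
#'   and `random_match_log10p` (`NA` here; populated by
#'   [random_match_probability()] / [match_samples()] when allele frequencies
#'   are available).
#' @export
concordance <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  shared <- intersect(a$loci, b$loci)
  if (length(shared) == 0L)
    stop("fingerprints share no loci", call. = FALSE)
  ca <- a$calls[match(shared, a$loci)]
  cb <- b$calls[match(shared, b$loci)]
  use <- !is.na(ca) & !is.na(cb)
  if (!any(use))
    stop("insufficient overlap: no locus is called in both fingerprints",
         call. = FALSE)
  n_compared <- sum(use)
  n_concordant <- sum(ca[use] == cb[use])
  structure(list(n_compared = n_compared,
                 n_concordant = n_concordant,
                 concordance = n_concordant / n_compared,
                 random_match_log10p = NA_real_),
            class = "match_result")
}

#' Random match probability of a genotype profile
#'
#' The forensic product rule under HWE and locus independence: the probability
#' that a random unrelated individual carries the observed multi-locus
#' profile is the product over called loci of the HWE genotype frequency of
#' the observed call (CC -> f_C^2, CD -> 2 f_C f_D, DD -> f_D^2), reported as
#' log10. Linked CpG loci violate the independence assumption, so treat the
#' value as an upper bound on surprise, not a likelihood-ratio verdict.
#'
#' @param fp a `fingerprint`.
#' @param freqs named numeric vector mapping probe IDs to the D-allele
#'   frequency `f_D`; every called fingerprint locus must be present, with
#'   `0 < f_D < 1`.
#' @return log10 probability (<= 0), with attributes `n_used` and
#'   `n_missing_skipped`.
#' @export
random_match_probability <- function(fp, freqs) {
  stopifnot(inherits(fp, "fingerprint"))
  used <- !is.na(fp$calls)
  loci <- fp$loci[used]
  calls <- fp$calls[used]
  absent <- setdiff(loci, names(freqs))
  if (length(absent))
    stop("no allele frequency for locus: ",
         paste(head(absent, 5L), collapse = ", "), call. = FALSE)
  f_d <- unname(freqs[loci])
  degenerate <- f_d <= 0 | f_d >= 1
  if (any(degenerate))
    stop("degenerate allele frequency (0 or 1) at locus: ",
         paste(head(loci[degenerate], 5L), collapse = ", "), call. = FALSE)
  f_c <- 1 - f_d
  g <- ifelse(calls == "CC", f_c^2,
              ifelse(calls == "CD", 2 * f_c * f_d, f_d^2))
  structure(sum(log10(g)),
            n_used = length(g), n_missing_skipped = sum(!used))
}

# integer recode (CC=1, CD=2, DD=3) for fast pairwise comparison
.calls_int <- function(calls) {
  array(match(unclass(calls), GENOTYPE_LEVELS), dim(calls), dimnames(calls))
}

#' Match samples between two genotyped datasets
#'
#' Scores every query x reference sample pair by genotype concordance over the
#' loci shared between the two call matrices, ranked best match first. Pairs
#' with fewer than `min_overlap` jointly called loci are omitted (their count
#' is reported as an attribute and a warning).
#'
#' @param query,reference [genotype_calls] matrices sharing at least one
#'   locus.
#' @param min_overlap minimum number of jointly called loci for a pair to be
#'   scored (default 30); guards against vacuous 100% matches.
#' @param freqs optional named `f_D` vector; when supplied, each pair's
#'   concordant-profile random-match probability is reported (log10, over loci
#'   called in both).
#' @return data.frame ranked by concordance, columns `query`, `reference`,
#'   `n_compared`, `n_concordant`, `concordance`, `random_match_log10p`;
#'   attribute `n_below_overlap` counts omitted pairs.
#' @export
match_samples <- function(query, reference, min_overlap = 30L, freqs = NULL) {
  shared <- intersect(rownames(query), rownames(reference))
  if (length(shared) == 0L)
    stop("query and reference share no loci", call. = FALSE)
  q <- .calls_int(query)[shared, , drop = FALSE]
  r <- .calls_int(reference)[shared, , drop = FALSE]
  pairs <- expand.grid(query = colnames(q), reference = colnames(r),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_compared <- n_concordant <- integer(nrow(pairs))
  log10p <- rep(NA_real_, nrow(pairs))
  f_d <- if (!is.null(freqs)) unname(freqs[shared])
  k <- 0L
  for (j in seq_len(ncol(r))) {
    rj <- r[, j]
    for (i in seq_len(ncol(q))) {
      k <- k + 1L
      use <- !is.na(q[, i]) & !is.na(rj)
      n_compared[k] <- sum(use)
      n_concordant[k] <- sum(q[use, i] == rj[use])
      if (!is.null(freqs) && n_compared[k] > 0L) {
        fd <- f_d[use]; fc <- 1 - fd
        g <- cbind(fc^2, 2 * fc * fd, fd^2)[cbind(seq_len(sum(use)), rj[use])]
        log10p[k] <- sum(log10(g))
      }
    }
  }
  res <- cbind(pairs,
               data.frame(n_compared = n_compared,
                          n_concordant = n_concordant,
                          concordance = ifelse(n_compared > 0,
                                               n_concordant / n_compared, NA),
                          random_match_log10p = log10p))
  drop <- res$n_compared < min_overlap
  if (any(drop))
    warning(sum(drop), " pair(s) below min_overlap = ", min_overlap,
            " omitted", call. = FALSE)
  res <- res[!drop, , drop = FALSE]
  res <- res[order(-res$concordance, -res$n_compared), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_below_overlap") <- sum(drop)
  res
}

#' Redact informative probes from a beta matrix
#'
#' The remediation step: remove the rows for genetically informative probes
#' before sharing a matrix. Removal (not masking) guarantees the genotype
#' signal is gone. Absent probe IDs are tolerated and reported.
#'
#' @param matrix a [beta_matrix].
#' @param probes character vector of probe IDs to remove.
#' @return list with `matrix` (the redacted [beta_matrix], same samples),
#'   `n_removed`, and `absent` (requested IDs that were not present).
#' @export
redact_probes <- function(matrix, probes) {
  present <- intersect(probes, rownames(matrix))
  keep <- setdiff(rownames(matrix), present)
  out <- unclass(matrix)[keep, , drop = FALSE]
  list(matrix = beta_matrix(out),
       n_removed = length(present),
       absent = setdiff(probes, present))
}
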