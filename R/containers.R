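#' Construct a beta matrix
#'
#' A beta matrix is the central input of the audit: a probes x samples numeric
#' matrix of methylation fractions in \[0,1\], with `NA` for missing entries.
#' The constructor validates the container invariants and attaches the
#' `"beta_matrix"` class; the object remains an ordinary matrix, so all base
#' subsetting and arithmetic keep working.
#'
#' @param values numeric matrix with unique rownames (probe IDs) and unique
#'   colnames (sample IDs); entries in \[0,1\] or `NA`.
#' @return a `beta_matrix` (numeric matrix subclass).
#' @examples
#' m <- beta_matrix(matrix(c(0.9, 0.5, 0.1, 0.95), 2, 2,
#'                         dimnames = list(c("cg1", "cg2"), c("s1", "s2"))))
#' @export
beta_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("beta matrix values must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("beta matrix needs probe IDs as rownames and sample IDs as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  bad <- which(!is.na(values) & (values < 0 | values > 1))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(values))
    stop(sprintf(
      "beta value %g outside [0,1] at probe '%s', sample '%s'",
      values[bad[1]], rownames(values)[i[1]], colnames(values)[i[2]]),
      call. = FALSE)
  }
  structure(values, class = c("beta_matrix", class(values)))
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  print(head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE],
             4L), ...)
  invisible(x)
}

GENOTYPE_LEVELS <- c("CC", "CD", "DD")

#' Construct a genotype call matrix
#'
#' Per-probe, per-sample categorical calls. `CC` is the intact, methylated CpG
#' on both chromosomes; `D` is the unidentified non-C base (A/G/T) of a
#' CpG-destroying polymorphism; `NA` covers both missing betas and values that
#' fell outside the three genotype bins.
#'
#' @param calls character matrix with values in `c("CC","CD","DD")` or `NA`,
#'   rownames = probe IDs, colnames = sample IDs.
#' @return a `genotype_calls` (character matrix subclass).
#' @export
genotype_calls <- function(calls) {
  if (!is.matrix(calls) || !is.character(calls))
    stop("genotype calls must be a character matrix", call. = FALSE)
  if ((nrow(calls) > 0L && is.null(rownames(calls))) ||
      (ncol(calls) > 0L && is.null(colnames(calls))))
    stop("genotype call matrix needs probe and sample IDs", call. = FALSE)
  bad <- setdiff(unique(calls[!is.na(calls)]), GENOTYPE_LEVELS)
  if (length(bad))
    stop("invalid genotype call(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(calls, class = c("genotype_calls", class(calls)))
}

#' @export
print.genotype_calls <- function(x, ...) {
  cat(sprintf("genotype_calls: %d probes x %d samples\n", nrow(x), ncol(x)))
  print(head(unclass(x)[, seq_len(min(ncol(x), 8L)), drop = FALSE], 4L), ...)
  invisible(x)
}
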