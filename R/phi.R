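# Protected-health-information flagging at trait-associated CpGs.
#
# Methylation at a handful of CpGs tracks exposures rather than genotype; the
# canonical example is cg05575921 in the aryl hydrocarbon receptor repressor
# (AHRR), where smokers are hypomethylated relative to nonsmokers. The flagger
# deliberately ships no numeric cutoffs: thresholds are study-dependent and
# must be supplied (and are echoed in the report) rather than invented here.

#' Define a trait-associated probe
#'
#' @param probe_id CpG probe identifier.
#' @param trait_label free-text trait name (e.g. `"smoking"`).
#' @param direction `"lower_in_positive"` if trait-positive subjects have
#'   lower beta (the AHRR/smoking case), else `"higher_in_positive"`.
#' @param threshold decision boundary in \[0,1\], or `NULL` (extraction works
#'   without one; flagging requires one).
#' @return a `trait_probe` list.
#' @export
trait_probe <- function(probe_id, trait_label,
                        direction = c("lower_in_positive",
                                      "higher_in_positive"),
                        threshold = NULL) {
  direction <- match.arg(direction)
  if (!is.null(threshold) &&
      (!is.numeric(threshold) || threshold < 0 || threshold > 1))
    stop("threshold must be in [0,1] when set", call. = FALSE)
  structure(list(probe_id = probe_id, trait_label = trait_label,
                 direction = direction, threshold = threshold),
            class = "trait_probe")
}

#' The default trait panel
#'
#' A single entry: cg05575921 (AHRR), smoking, hypomethylated in smokers, no
#' threshold. Alcohol-responsive loci are documented elsewhere in the
#' literature but no specific probes are bundled here.
#'
#' @return list of [trait_probe] objects.
#' @export
default_trait_panel <- function() {
  list(trait_probe("cg05575921", "smoking", "lower_in_positive"))
}

#' Extract beta values at trait-associated probes
#'
#' @param matrix a [beta_matrix].
#' @param panel list of [trait_probe] objects (default [default_trait_panel()]).
#' @return long data.frame (`sample_id`, `probe_id`, `trait`, `beta`), one row
#'   per (sample, assayed panel probe); missing betas preserved as `NA`.
#'   Attribute `not_assayed` lists panel probes absent from the matrix.
#' @export
extract_trait_betas <- function(matrix, panel = default_trait_panel()) {
  if (length(panel) == 0L) {
    warning("empty trait panel", call. = FALSE)
    return(structure(data.frame(sample_id = character(), probe_id = character(),
                                trait = character(), beta = numeric()),
                     not_assayed = character()))
  }
  ids <- vapply(panel, `[[`, "", "probe_id")
  traits <- vapply(panel, `[[`, "", "trait_label")
  present <- ids %in% rownames(matrix)
  rows <- lapply(which(present), function(i)
    data.frame(sample_id = colnames(matrix), probe_id = ids[i],
               trait = traits[i],
               beta = unname(unclass(matrix)[ids[i], ]),
               stringsAsFactors = FALSE))
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(sample_id = character(), probe_id = character(),
                  trait = character(), beta = numeric())
  rownames(out) <- NULL
  structure(out, not_assayed = ids[!present])
}

#' Flag trait status from a beta value
#'
#' Vectorised over `beta`. For `lower_in_positive`: beta strictly below the
#' threshold is `positive`, at or above is `negative`; mirrored for
#' `higher_in_positive`. Missing beta is `indeterminate`.
#'
#' @param beta numeric vector of beta values (`NA` allowed).
#' @param probe a [trait_probe] with its `threshold` set.
#' @return character vector over `c("positive","negative","indeterminate")`.
#' @export
flag_trait_status <- function(beta, probe) {
  stopifnot(inherits(probe, "trait_probe"))
  if (is.null(probe$threshold))
    stop("no threshold set for trait '", probe$trait_label,
         "': supply trait_probe(..., threshold = ) — no clinical cutoff ",
         "ships with this package", call. = FALSE)
  if (any(!is.na(beta) & (beta < 0 | beta > 1)))
    stop("beta value(s) outside [0,1]", call. = FALSE)
  below <- beta < probe$threshold
  pos <- if (probe$direction == "lower_in_positive") below else !below
  out <- ifelse(pos, "positive", "negative")
  out[is.na(beta)] <- "indeterminate"
  out
}
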