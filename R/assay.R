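# In-silico MspI restriction-digest assay design.
#
# MspI cuts C^CGG (after the first C), methylation-insensitively, on genomic
# DNA. When the assayed CpG is the inner CG of a CCGG tetramer, a C->D
# polymorphism at the CpG cytosine destroys the site: the C allele cuts, the
# D allele does not, and fragment patterns on a gel read out the genotype —
# an orthogonal wet-lab validation of array-inferred calls.

MSPI_SITE <- "CCGG"

#' Find MspI recognition sites in a sequence
#'
#' @param sequence uppercase A/C/G/T string.
#' @return integer vector of 0-based start positions of every (possibly
#'   overlapping) `CCGG` occurrence, ascending.
#' @examples
#' find_mspi_sites("ATCCGGAT")   # 2
#' find_mspi_sites("CCGGCCGG")   # 0 4
#' @export
find_mspi_sites <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence))
    stop("sequence must be a single string", call. = FALSE)
  if (grepl("[^ACGT]", sequence))
    stop("sequence contains non-ACGT characters", call. = FALSE)
  hits <- gregexpr(paste0("(?=", MSPI_SITE, ")"), sequence, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits) - 1L
}

#' Is the assayed CpG recognisable by MspI?
#'
#' TRUE iff the assayed CpG is the inner CG of a CCGG tetramer, i.e. its C is
#' preceded by a C and its G followed by a G in the probe source sequence. A
#' CpG too close to the sequence edge to form the tetramer returns FALSE with
#' a warning.
#'
#' @param annotation one row of a [read_annotation()] table, or any list with
#'   `source_sequence` and 0-based `cpg_offset`.
#' @return logical.
#' @export
cpg_is_mspi_assayable <- function(annotation) {
  seq <- annotation$source_sequence
  off <- annotation$cpg_offset  # 0-based index of the CpG's C
  stopifnot(length(seq) == 1L, length(off) == 1L)
  if (substr(seq, off + 1L, off + 2L) != "CG")
    stop("annotation invariant violated: no CG at cpg_offset", call. = FALSE)
  if (off < 1L || off + 3L > nchar(seq)) {
    warning("assayed CpG at the sequence edge cannot form a CCGG tetramer",
            call. = FALSE)
    return(FALSE)
  }
  substr(seq, off, off + 3L) == MSPI_SITE
}

#' Define a digest assay
#'
#' Models a PCR amplicon containing the assayed CpG, with exactly one
#' genotype-dependent (target) MspI site; all other CCGG sites in the amplicon
#' are assumed invariant and cut on every allele.
#'
#' @param probe_id probe whose genotype the assay validates.
#' @param amplicon_sequence uppercase A/C/G/T amplicon.
#' @param target_cpg_position 0-based position of the assayed CpG's C within
#'   the amplicon; must be the inner CG of a CCGG site.
#' @return a `digest_assay` list with `site_positions` (all CCGG starts) and
#'   `target_site_index` (which of them is genotype-dependent).
#' @export
digest_assay <- function(probe_id, amplicon_sequence, target_cpg_position) {
  sites <- find_mspi_sites(amplicon_sequence)
  if (length(sites) == 0L)
    stop("assay design error: amplicon contains no CCGG site", call. = FALSE)
  target <- which(sites == target_cpg_position - 1L)  # site starts at C before the CpG
  if (length(target) != 1L)
    stop("assay design error: the assayed CpG at position ",
         target_cpg_position, " is not the inner CG of a CCGG site",
         call. = FALSE)
  structure(list(probe_id = probe_id,
                 amplicon_sequence = amplicon_sequence,
                 site_positions = sites,
                 target_site_index = target),
            class = "digest_assay")
}

#' Predict digest fragment lengths by genotype
#'
#' The C allele is cut at the target site, the D allele is not; constitutive
#' sites are cut on both alleles. MspI cuts after the first C of CCGG
#' (C^CGG); only fragment lengths are modeled, not sticky ends. A
#' heterozygote's lane shows the union of the two allele patterns.
#'
#' @param assay a [digest_assay].
#' @param genotype `"CC"`, `"CD"` or `"DD"`.
#' @return sorted integer vector of expected fragment lengths (a multiset:
#'   lengths may repeat); per allele the lengths sum to the amplicon length.
#' @examples
#' a <- digest_assay("cgX", paste0(strrep("A", 40), "CCGG", strrep("T", 56)), 41)
#' predict_digest(a, "CC")  # 41 59
#' predict_digest(a, "DD")  # 100
#' predict_digest(a, "CD")  # 41 59 100
#' @export
predict_digest <- function(assay, genotype = c("CC", "CD", "DD")) {
  stopifnot(inherits(assay, "digest_assay"))
  genotype <- match.arg(genotype)
  len <- nchar(assay$amplicon_sequence)
  cuts_at <- function(sites) sort(sites + 1L)  # cut after the first C
  fragments <- function(sites) {
    bounds <- c(0L, cuts_at(sites), len)
    diff(bounds)
  }
  all_sites <- assay$site_positions
  const_sites <- all_sites[-assay$target_site_index]
  c_allele <- fragments(all_sites)
  d_allele <- fragments(const_sites)
  out <- switch(genotype,
                CC = c_allele,
                DD = d_allele,
                CD = c(c_allele, d_allele))
  sort(out)
}

#' PCR primers for the two wet-lab-validated loci
#'
#' Returns the packaged primer table for the two probes whose array-inferred
#' genotypes were confirmed by MspI digestion of PCR amplicons (cg10695549
#' and cg21028319).
#'
#' @return data.frame with columns `probe_id`, `forward`, `reverse`.
#' @export
validated_primers <- function() {
  path <- system.file("extdata", "mspi_primers.tsv", package = "methylaudit",
                      mustWork = TRUE)
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                    colClasses = "character")
}
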