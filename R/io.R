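# Tabular I/O. Parsing is delegated to data.table::fread; this file owns the
# dialect framing (GEO series-matrix markers), missing-token policy, and the
# domain validation that fread cannot do.

# Missing tokens accepted on read (case-insensitive). "null" is the GEO
# series-matrix convention; the others cover hand-made TSVs.
MISSING_TOKENS <- c("", "na", "nan", "null")

#' Read a beta matrix from disk
#'
#' Two dialects are supported: a plain TSV (header row of sample IDs, first
#' column of probe IDs) and the GEO series-matrix format, where the same table
#' is delimited by `!series_matrix_table_begin` / `!series_matrix_table_end`
#' marker lines and headed by an `ID_REF` column.
#'
#' Empty cells and the tokens `NA`, `NaN`, `null` (case-insensitive) become
#' missing values. Any other non-numeric cell is a parse error naming the
#' offending probe and sample; any value outside \[0,1\] is a domain error.
#' Probe and sample order is preserved exactly; no row is ever dropped.
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"geo_series_matrix"` (alias `"geo"`).
#' @return a [beta_matrix].
#' @export
read_beta_matrix <- function(path, format = c("tsv", "geo_series_matrix", "geo")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = "character", na.strings = NULL,
                            data.table = TRUE, showProgress = FALSE)
  } else {
    # locate the table inside the series-matrix framing; fread's skip= finds
    # the ID_REF header line without loading the metadata block
    # fread warns while discarding the single-line end marker; that is the
    # expected framing, not a data problem
    dt <- withCallingHandlers(
      data.table::fread(path, sep = "\t", header = TRUE, skip = "ID_REF",
                        colClasses = "character", na.strings = NULL,
                        blank.lines.skip = TRUE,
                        data.table = TRUE, showProgress = FALSE),
      warning = function(w) {
        if (grepl("footer", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    dt <- dt[!startsWith(dt[[1L]], "!")]
  }
  if (ncol(dt) < 2L) stop("beta table has no sample columns", call. = FALSE)
  probe_ids <- dt[[1L]]
  sample_ids <- colnames(dt)[-1L]
  if (anyDuplicated(probe_ids))
    stop("duplicate probe ID(s) in ", path, ": ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "),
         call. = FALSE)
  raw <- as.matrix(dt[, -1L, with = FALSE])
  is_missing <- matrix(tolower(trimws(raw)) %in% MISSING_TOKENS, nrow(raw))
  vals <- suppressWarnings(array(as.numeric(raw), dim(raw)))
  bad <- which(is.na(vals) & !is_missing)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(vals))
    stop(sprintf("cannot parse cell '%s' at probe '%s', sample '%s'",
                 raw[bad[1L]], probe_ids[i[1L]], sample_ids[i[2L]]),
         call. = FALSE)
  }
  vals[is_missing] <- NA_real_
  dimnames(vals) <- list(probe_ids, sample_ids)
  beta_matrix(vals)
}

# case/punctuation-insensitive column lookup: "Position (bp)" matches "position"
.find_column <- function(nms, candidates) {
  key <- gsub("[^a-z0-9]", "", tolower(nms))
  for (cand in candidates) {
    hit <- which(key == cand | startsWith(key, cand))
    if (length(hit)) return(hit[1L])
  }
  NA_integer_
}

#' Read a probe annotation table
#'
#' Accepts a delimited (CSV or TSV) table with at least probe ID, chromosome,
#' Build-37 position, and probe source sequence columns; an optional
#' `cpg_offset` column gives the 0-based index of the assayed CpG's C within
#' the source sequence. When absent, the offset is derived as the first `CG`
#' in the sequence, with a warning for sequences holding more than one
#' candidate CpG. Coordinates are 1-based Genome Build 37 positions of the
#' targeted cytosine.
#'
#' @param path path to the file (delimiter auto-detected).
#' @return a data.frame (class `probe_annotation`) with columns `probe_id`,
#'   `chromosome`, `position_bp`, `source_sequence`, `cpg_offset`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          data.table = FALSE, showProgress = FALSE)
  cols <- c(probe_id  = .find_column(names(dt), c("probeid", "ilmnid", "name", "id")),
            chromosome = .find_column(names(dt), c("chromosome", "chr")),
            position_bp = .find_column(names(dt), c("positionbp", "position", "mapinfo", "pos")),
            source_sequence = .find_column(names(dt), c("sourcesequence", "sequence", "sourceseq")))
  if (anyNA(cols))
    stop("annotation table is missing column(s): ",
         paste(names(cols)[is.na(cols)], collapse = ", "), call. = FALSE)
  ann <- data.frame(probe_id = dt[[cols["probe_id"]]],
                    chromosome = dt[[cols["chromosome"]]],
                    position_bp = as.integer(dt[[cols["position_bp"]]]),
                    source_sequence = toupper(dt[[cols["source_sequence"]]]),
                    stringsAsFactors = FALSE)
  off_col <- .find_column(names(dt), "cpgoffset")
  if (!is.na(off_col)) {
    ann$cpg_offset <- as.integer(dt[[off_col]])
  } else {
    hits <- gregexpr("CG", ann$source_sequence, fixed = TRUE)
    ann$cpg_offset <- vapply(hits, function(h) h[1L] - 1L, integer(1))
    multi <- vapply(hits, function(h) h[1L] != -1L && length(h) > 1L, logical(1))
    if (any(multi))
      warning(sum(multi), " probe(s) have more than one CG in their source ",
              "sequence; the first occurrence was taken as the assayed CpG",
              call. = FALSE)
  }
  at_cpg <- substr(ann$source_sequence, ann$cpg_offset + 1L, ann$cpg_offset + 2L)
  bad <- is.na(ann$cpg_offset) | ann$cpg_offset < 0L | at_cpg != "CG"
  if (any(bad))
    stop("source sequence lacks a CG at the stated offset for probe(s): ",
         paste(ann$probe_id[bad], collapse = ", "), call. = FALSE)
  if (any(is.na(ann$position_bp) | ann$position_bp < 1L))
    stop("position_bp must be a 1-based positive coordinate; offending probe(s): ",
         paste(ann$probe_id[is.na(ann$position_bp) | ann$position_bp < 1L],
               collapse = ", "), call. = FALSE)
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Write / read a genotype call matrix
#'
#' TSV with probes as rows, samples as columns, cells in `CC`/`CD`/`DD`/`NA`.
#' `write_genotype_matrix()` followed by `read_genotype_matrix()` is a lossless
#' round trip.
#'
#' @param calls a [genotype_calls] matrix (nonempty).
#' @param path output (or input) path.
#' @return `write_genotype_matrix()` returns `path` invisibly;
#'   `read_genotype_matrix()` returns a [genotype_calls] matrix.
#' @export
write_genotype_matrix <- function(calls, path) {
  calls <- genotype_calls(unclass(calls))
  if (nrow(calls) == 0L || ncol(calls) == 0L)
    stop("refusing to write an empty genotype matrix", call. = FALSE)
  dt <- data.table::data.table(probe_id = rownames(calls))
  for (s in colnames(calls)) data.table::set(dt, j = s, value = calls[, s])
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          na.strings = c("", "NA"),
                          data.table = FALSE, showProgress = FALSE)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(m) <- dt[[1L]]
  genotype_calls(m)
}
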