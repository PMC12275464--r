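# Overlap between the methylation partition and an orthogonal assignment.

# Accepts a BAM path (mapped primary read ids), a text file of ids (one per
# line), or a plain character vector of ids.
.read_id_set <- function(x, strip_suffix = TRUE) {
  ids <- if (is.character(x) && length(x) == 1L && file.exists(x)) {
    if (grepl("\\.bam$", x, ignore.case = TRUE)) {
      res <- Rsamtools::scanBam(
        x,
        param = Rsamtools::ScanBamParam(
          what = "qname",
          flag = Rsamtools::scanBamFlag(
            isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
            isSupplementaryAlignment = FALSE)))[[1]]$qname
    } else {
      readLines(x, warn = FALSE)
    }
  } else {
    as.character(x)
  }
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  if (strip_suffix) ids <- sub("/[12]$", "", ids)
  unique(ids)
}

#' Overlap between two read sets
#'
#' Quantifies agreement between two read assignments, e.g. the methylated
#' (`plus_m`) partition versus reads that realign to the nuclear genome
#' with NuMTs unmasked and chrM masked. The fraction is computed relative
#' to the *reference* set (by convention the orthogonal, realigned set);
#' swap the arguments to invert the denominator.
#'
#' @param reference,query Each a BAM path, a text file of read ids (one
#'   per line), or a character vector of ids. Duplicates are collapsed and
#'   `/1`,`/2` suffixes stripped.
#' @param strip_suffix Strip trailing `/1`/`/2` from read ids?
#' @return An `overlap_report` object: `n_reference_set`, `n_query_set`,
#'   `n_overlap`, `overlap_fraction = n_overlap / n_reference_set`.
#' @examples
#' overlap_report(c("r1", "r2", "r3"), c("r2", "r3", "r4"))
#' @export
overlap_report <- function(reference, query, strip_suffix = TRUE) {
  ref <- .read_id_set(reference, strip_suffix)
  qry <- .read_id_set(query, strip_suffix)
  if (!length(ref)) {
    ms_stop("reference read set is empty; overlap fraction is undefined",
            "ms_input_error")
  }
  n_ov <- length(intersect(ref, qry))
  structure(list(
    n_reference_set = length(ref),
    n_query_set = length(qry),
    n_overlap = n_ov,
    overlap_fraction = n_ov / length(ref)
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "read-set overlap: %d of %d reference reads in query (%.1f%%; query size %d)\n",
    x$n_overlap, x$n_reference_set, 100 * x$overlap_fraction, x$n_query_set))
  invisible(x)
}
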