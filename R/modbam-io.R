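# BAM-level modified-base I/O built on Rsamtools.

#' Load modified-base alignment records from a BAM file
#'
#' Reads mapped records (secondary alignments are always excluded) together
#' with their MM/ML tags (legacy Mm/Ml spellings accepted) and precomputes
#' the as-sequenced orientation of each sequence: MM positions refer to the
#' read as it came off the sequencer, so reverse-strand records are
#' reverse-complemented.
#'
#' @param bam Path to a BAM file.
#' @param include_supplementary Keep supplementary records (flag 0x800)?
#' @return A list of parallel vectors: `qname`, `flag`, `rname`, `pos`,
#'   `cigar`, `seq_aligned` (stored SEQ), `seq_as_sequenced`, `mm`
#'   (character, `NA` when absent), `ml` (list of integer vectors or
#'   `NULL`), `is_reverse`, `is_supplementary`, and the record count `n`.
#' @export
scan_modbam <- function(bam, include_supplementary = FALSE) {
  if (!file.exists(bam)) {
    ms_stop(paste0("BAM file not found: ", bam), "ms_input_error")
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("MM", "ML", "Mm", "Ml"),
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = if (include_supplementary) NA else FALSE
    )
  )
  res <- Rsamtools::scanBam(Rsamtools::BamFile(bam), param = param)[[1]]
  n <- length(res$qname)

  mm <- res$tag$MM %||% rep(NA_character_, n)
  if (!is.null(res$tag$Mm)) {
    mm[is.na(mm)] <- res$tag$Mm[is.na(mm)]
  }
  norm_ml <- function(x) {
    if (is.null(x)) return(vector("list", n))
    lapply(x, function(v) if (is.numeric(v)) as.integer(v) else NULL)
  }
  ml <- norm_ml(res$tag$ML)
  if (!is.null(res$tag$Ml)) {
    alt <- norm_ml(res$tag$Ml)
    miss <- vapply(ml, is.null, logical(1))
    ml[miss] <- alt[miss]
  }

  seqs <- as.character(res$seq)
  is_rev <- bitwAnd(res$flag, 16L) > 0L
  is_supp <- bitwAnd(res$flag, 2048L) > 0L
  seq_as <- seqs
  if (any(is_rev)) seq_as[is_rev] <- revcomp(seqs[is_rev])

  list(
    qname = res$qname, flag = res$flag, rname = as.character(res$rname),
    pos = res$pos, cigar = res$cigar,
    seq_aligned = seqs, seq_as_sequenced = seq_as,
    mm = mm, ml = ml,
    is_reverse = is_rev, is_supplementary = is_supp, n = n
  )
}

#' Strip modification codes from every record of a BAM file
#'
#' Applies [strip_modification()] (e.g. removing 5hmC so only 5mC remains)
#' to every alignment record, writing a new coordinate-sorted and indexed
#' BAM. Records without MM/ML, or without a stored sequence, pass through
#' unchanged.
#'
#' @param in_bam,out_bam Input and output BAM paths (must differ).
#' @param codes_to_remove Character vector of modification codes, e.g. `"h"`.
#' @param policy `"drop"` or `"merge_into_m"`; see [strip_modification()].
#' @return `out_bam`, invisibly.
#' @export
strip_modification_bam <- function(in_bam, out_bam, codes_to_remove = "h",
                                   policy = c("drop", "merge_into_m")) {
  policy <- match.arg(policy)
  if (!file.exists(in_bam)) {
    ms_stop(paste0("BAM file not found: ", in_bam), "ms_input_error")
  }
  if (normalizePath(in_bam, mustWork = FALSE) ==
      normalizePath(out_bam, mustWork = FALSE)) {
    ms_stop("input and output BAM must differ", "ms_config_error")
  }
  sam <- Rsamtools::asSam(in_bam, tempfile())
  on.exit(unlink(sam), add = TRUE)
  lines <- readLines(sam)
  is_aln <- !startsWith(lines, "@")
  idx <- which(is_aln)
  for (i in idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    tags <- f[-seq_len(11)]
    mm_at <- which(startsWith(tags, "MM:Z:") | startsWith(tags, "Mm:Z:"))
    if (!length(mm_at) || f[10] == "*") next
    ml_at <- which(startsWith(tags, "ML:B:C") | startsWith(tags, "Ml:B:C"))
    mm_val <- substring(tags[mm_at[1]], 6L)
    ml_val <- if (length(ml_at)) {
      s <- sub("^M[Ll]:B:C,?", "", tags[ml_at[1]])
      if (nzchar(s)) as.integer(strsplit(s, ",", fixed = TRUE)[[1]]) else NULL
    } else {
      NULL
    }
    flag <- as.integer(f[2])
    seq_as <- if (bitwAnd(flag, 16L) > 0L) revcomp(f[10]) else f[10]
    rec <- strip_modification(
      list(read_id = f[1], seq = seq_as, mm = mm_val, ml = ml_val),
      codes_to_remove, policy
    )
    drop_at <- sort(c(mm_at, ml_at))
    tags <- if (length(drop_at)) tags[-drop_at] else tags
    if (nzchar(rec$mm)) {
      tags <- c(tags, paste0("MM:Z:", rec$mm))
      if (!is.null(rec$ml)) {
        tags <- c(tags, paste0("ML:B:C,", paste(rec$ml, collapse = ",")))
      }
    }
    lines[i] <- paste(c(f[seq_len(11)], tags), collapse = "\t")
  }
  out_sam <- tempfile(fileext = ".sam")
  on.exit(unlink(out_sam), add = TRUE)
  writeLines(lines, out_sam)
  sam_to_bam(out_sam, out_bam)
  invisible(out_bam)
}
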