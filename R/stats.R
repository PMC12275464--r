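# Per-BAM summary statistics and the read-methylation histogram.

.base_counts <- function(x) {
  Biostrings::letterFrequency(Biostrings::DNAStringSet(x),
                              c("A", "C", "G", "T"))
}

#' Strand-composition skew of DNA sequences
#'
#' `gc_skew()` computes `(G - C) / (G + C)` and `at_skew()`
#' `(A - T) / (A + T)` per sequence, ignoring N. The human mitochondrial
#' forward strand has a strongly negative GC skew (about -0.35), which
#' makes skew a useful orthogonal check on read origin. Sequences without
#' any G/C (resp. A/T) return `NA`.
#'
#' @param seq Character vector of DNA sequences.
#' @return Numeric vector in `[-1, 1]`, `NA` where undefined.
#' @examples
#' gc_skew("GGGC")  # 0.5
#' @export
gc_skew <- function(seq) {
  m <- .base_counts(seq)
  s <- (m[, "G"] - m[, "C"]) / (m[, "G"] + m[, "C"])
  s[!is.finite(s)] <- NA_real_
  unname(s)
}

#' @rdname gc_skew
#' @export
at_skew <- function(seq) {
  m <- .base_counts(seq)
  s <- (m[, "A"] - m[, "T"]) / (m[, "A"] + m[, "T"])
  s[!is.finite(s)] <- NA_real_
  unname(s)
}

#' GC content of DNA sequences, in percent
#'
#' @param seq Character vector of DNA sequences; N is ignored.
#' @return Numeric vector of `(G + C) / (A + C + G + T) * 100`.
#' @export
gc_percent <- function(seq) {
  m <- .base_counts(seq)
  unname((m[, "G"] + m[, "C"]) / rowSums(m) * 100)
}

#' Summarise an aligned modBAM
#'
#' Computes the per-file summary block: unique mapped reads, mean depth of
#' coverage (aligned reference bases over reference length), per-read GC%,
#' GC and AT skew averaged unweighted across reads, read lengths, and
#' aggregate 5mC call counts. Skews and GC% are computed on the stored
#' (aligned-orientation) SEQ so that forward- and reverse-aligned reads of
#' the same strand origin agree instead of cancelling. `unmodified_c`
#' counts 5mC calls below `call_threshold`, `n_5mc` those at or above it;
#' `fraction_5mc = n_5mc / (unmodified_c + n_5mc)`.
#'
#' @param bam Path to an aligned BAM with MM/ML tags.
#' @param call_threshold Per-site 5mC probability cut-off (default 0.5).
#' @return A `modbam_summary` object (list) with the fields above plus
#'   `mean_read_length`, `median_read_length`, `reference`, and
#'   `reference_length`.
#' @export
summarize_bam <- function(bam, call_threshold = 0.5) {
  if (!file.exists(bam)) {
    ms_stop(paste0("BAM file not found: ", bam), "ms_input_error")
  }
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (is.null(targets) || !length(targets)) {
    ms_stop("BAM header lists no reference sequences", "ms_input_error")
  }
  d <- scan_modbam(bam, include_supplementary = TRUE)
  prim <- which(!d$is_supplementary)

  ref <- if (length(prim)) {
    names(which.max(table(factor(d$rname[prim], levels = names(targets)))))
  } else {
    names(targets)[1]
  }
  ref_len <- unname(targets[[ref]])
  on_ref <- d$rname == ref
  aligned_bases <- if (d$n) sum(cigar_ref_width(d$cigar[on_ref])) else 0

  seqs <- d$seq_aligned[prim]
  lens <- nchar(seqs)
  n_m <- 0L; n_u <- 0L
  for (i in prim) {
    dec <- decode_mod_tags(d$seq_as_sequenced[i], d$mm[i], d$ml[[i]],
                           read_id = d$qname[i])
    mc <- dec$calls[dec$calls$mod_code == "m", , drop = FALSE]
    n_m <- n_m + sum(mc$probability >= call_threshold)
    n_u <- n_u + sum(mc$probability < call_threshold)
  }
  structure(list(
    unique_reads = length(unique(d$qname[prim])),
    mean_coverage = aligned_bases / ref_len,
    gc_percent = if (length(seqs)) mean(gc_percent(seqs), na.rm = TRUE)
                 else NA_real_,
    mean_gc_skew = if (length(seqs)) mean(gc_skew(seqs), na.rm = TRUE)
                   else NA_real_,
    mean_at_skew = if (length(seqs)) mean(at_skew(seqs), na.rm = TRUE)
                   else NA_real_,
    mean_read_length = if (length(lens)) mean(lens) else NA_real_,
    median_read_length = if (length(lens)) median(lens) else NA_real_,
    unmodified_c = n_u,
    n_5mc = n_m,
    fraction_5mc = if (n_u + n_m > 0L) n_m / (n_u + n_m) else NA_real_,
    reference = ref,
    reference_length = ref_len,
    call_threshold = call_threshold
  ), class = "modbam_summary")
}

#' @export
print.modbam_summary <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else format(v, digits = 4)
  cat("modBAM summary (reference ", x$reference, ", ",
      x$reference_length, " bp)\n", sep = "")
  rows <- c(
    "UNIQUE READS" = x$unique_reads,
    "Coverage" = x$mean_coverage,
    "GC%" = x$gc_percent,
    "GC skew" = x$mean_gc_skew,
    "AT skew" = x$mean_at_skew,
    "Read length (mean)" = x$mean_read_length,
    "Read length (median)" = x$median_read_length,
    "Unmodified C" = x$unmodified_c,
    "5mC" = x$n_5mc,
    "Fraction 5mC (5mC/C + 5mC)" = x$fraction_5mc
  )
  for (nm in names(rows)) {
    cat(sprintf("  %-28s %s\n", nm, fmt(rows[[nm]])))
  }
  invisible(x)
}

#' @export
as.data.frame.modbam_summary <- function(x, ...) {
  as.data.frame(unclass(x)[seq_len(13)], stringsAsFactors = FALSE)
}

#' Histogram of per-read CpG methylation fractions
#'
#' Bins read methylation percentages into half-open bins of `bin_width`
#' percent (`[0, 5), [5, 10), ...`), with the last bin closed at 100. The
#' lowest bin's share is the headline quantity: in mtDNA-dominated data the
#' distribution is bimodal with most reads in `[0, 5)`.
#'
#' @param x Numeric vector of methylation fractions in `[0, 1]`, or a
#'   profile data frame from [screen_bam()] (rows labelled `no_cpg` are
#'   excluded).
#' @param bin_width Bin width in percent; must divide 100 (default 5).
#' @return A `methylation_histogram` data frame with columns `bin_start`,
#'   `bin_end`, `count`, `share`.
#' @export
methylation_histogram <- function(x, bin_width = 5) {
  if (is.data.frame(x)) {
    x <- x$methylation_fraction[x$label != "no_cpg"]
  }
  if (!is.numeric(bin_width) || length(bin_width) != 1L ||
      bin_width <= 0 || 100 %% bin_width != 0) {
    ms_stop("bin_width must be a positive divisor of 100",
            "ms_config_error")
  }
  x <- x[!is.na(x)]
  if (any(x < 0 | x > 1)) {
    ms_stop("methylation fractions must lie in [0, 1]", "ms_config_error")
  }
  nb <- as.integer(100 / bin_width)
  idx <- pmin(floor(x * 100 / bin_width) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  out <- data.frame(
    bin_start = bin_width * (seq_len(nb) - 1L),
    bin_end = bin_width * seq_len(nb),
    count = counts,
    share = if (length(x)) counts / length(x) else rep(NA_real_, nb)
  )
  class(out) <- c("methylation_histogram", "data.frame")
  out
}
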