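# Per-read CpG methylation screening and BAM partitioning.

#' Find CpG sites in a read sequence
#'
#' @param read_seq DNA string over A/C/G/T/N.
#' @return 0-based positions of the C in every CG dinucleotide.
#' @examples
#' cpg_sites("ACGTCG")  # 1, 4
#' @export
cpg_sites <- function(read_seq) {
  hits <- gregexpr("CG", read_seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer() else as.integer(hits) - 1L
}

#' Classify a per-read methylation fraction
#'
#' Reads strictly below the split threshold are labelled `minus_m`
#' (putative mtDNA); reads at or above it `plus_m` (putative NuMT); reads
#' without an assessable CpG (`NA` fraction) `no_cpg`. The boundary goes to
#' `plus_m`: a read at exactly the threshold is treated as methylated.
#'
#' @param fraction Numeric vector of methylation fractions in `[0, 1]`
#'   (`NA`/`NaN` for reads without CpG calls).
#' @param split_threshold Single value in `[0, 1]`; default 0.15.
#' @return Character vector of labels.
#' @export
classify_read <- function(fraction, split_threshold = 0.15) {
  if (!is.numeric(split_threshold) || length(split_threshold) != 1L ||
      is.na(split_threshold) || split_threshold < 0 || split_threshold > 1) {
    ms_stop("split_threshold must be a single value in [0, 1]",
            "ms_config_error")
  }
  ifelse(is.na(fraction), "no_cpg",
         ifelse(fraction < split_threshold, "minus_m", "plus_m"))
}

#' Quantify CpG methylation of a single read
#'
#' Decodes the record's MM/ML tags and scores every 5mC (`m`) call that
#' falls on a CpG cytosine of the read's own sequence: a site counts as
#' methylated when its probability is at or above `call_threshold`. Under
#' the implicit MM dialect (`.` or no flag) uncalled CpG cytosines are
#' asserted unmodified by the basecaller and enter the denominator; under
#' the explicit dialect (`?`) only called sites are assessed. Calls at
#' non-CpG positions are ignored and tallied in `n_noncpg_calls`.
#'
#' @param record List with `read_id`, `seq` (as-sequenced orientation),
#'   `mm`, `ml`.
#' @param call_threshold Per-site 5mC probability cut-off; default 0.5.
#' @param split_threshold Read-level split threshold used for the label.
#' @param confidence_band Optional length-2 numeric `c(low, high)`: sites
#'   with probability strictly inside the band are treated as unassessable
#'   and removed from both counts. Off (`NULL`) by default.
#' @return One-row data frame: `read_id`, `n_cpg_assessed`, `n_methylated`,
#'   `methylation_fraction`, `n_noncpg_calls`, `label`.
#' @export
read_methylation_fraction <- function(record, call_threshold = 0.5,
                                      split_threshold = 0.15,
                                      confidence_band = NULL) {
  if (is.null(record$seq) || is.na(record$seq) || !nzchar(record$seq) ||
      identical(record$seq, "*")) {
    ms_stop(sprintf("read %s has no stored sequence",
                    record$read_id %||% "<unnamed>"), "ms_input_error")
  }
  dec <- decode_mod_tags(record$seq, record$mm, record$ml,
                         read_id = record$read_id)
  calls <- dec$calls
  mcalls <- calls[calls$mod_code == "m" & calls$mod_strand == "+" &
                  calls$canonical_base == "C", , drop = FALSE]
  cpg <- cpg_sites(record$seq)
  in_cpg <- mcalls$position %in% cpg
  probs <- mcalls$probability[in_cpg]
  n_filtered <- 0L
  if (!is.null(confidence_band)) {
    low_conf <- probs > confidence_band[1] & probs < confidence_band[2]
    n_filtered <- sum(low_conf)
    probs <- probs[!low_conf]
  }
  runs <- dec$runs
  m_run <- grepl("m", runs$mod_codes, fixed = TRUE) &
    !grepl("^[0-9]+$", runs$mod_codes) &
    runs$canonical_base == "C" & runs$mod_strand == "+"
  implicit <- any(m_run & runs$skip_mode == "implicit")
  n_assessed <- if (implicit) length(cpg) - n_filtered
                else length(probs)
  n_meth <- sum(probs >= call_threshold)
  frac <- if (n_assessed > 0L) n_meth / n_assessed else NA_real_
  data.frame(
    read_id = record$read_id %||% NA_character_,
    n_cpg_assessed = as.integer(n_assessed),
    n_methylated = as.integer(n_meth),
    methylation_fraction = frac,
    n_noncpg_calls = sum(!in_cpg),
    label = classify_read(frac, split_threshold),
    stringsAsFactors = FALSE
  )
}

#' Screen every read of a modBAM for CpG methylation
#'
#' Applies [read_methylation_fraction()] to each mapped primary record.
#' Supplementary records are excluded here; [split_bam()] routes them by
#' their primary's label.
#'
#' @param bam Path to an aligned BAM with MM/ML tags.
#' @param call_threshold Per-site 5mC probability cut-off (default 0.5).
#' @param split_threshold Read-level methylation threshold (default 0.15).
#' @param min_cpg Reads with fewer assessed CpGs than this are labelled
#'   `no_cpg` (default 1, i.e. only reads with zero assessable CpGs).
#' @param confidence_band Passed to [read_methylation_fraction()].
#' @return Data frame of per-read profiles, one row per read.
#' @export
screen_bam <- function(bam, call_threshold = 0.5, split_threshold = 0.15,
                       min_cpg = 1L, confidence_band = NULL) {
  d <- scan_modbam(bam, include_supplementary = FALSE)
  rows <- vector("list", d$n)
  for (i in seq_len(d$n)) {
    rows[[i]] <- read_methylation_fraction(
      list(read_id = d$qname[i], seq = d$seq_as_sequenced[i],
           mm = d$mm[i], ml = d$ml[[i]]),
      call_threshold = call_threshold, split_threshold = split_threshold,
      confidence_band = confidence_band
    )
  }
  if (!length(rows)) {
    return(data.frame(
      read_id = character(), n_cpg_assessed = integer(),
      n_methylated = integer(), methylation_fraction = double(),
      n_noncpg_calls = integer(), label = character(),
      stringsAsFactors = FALSE
    ))
  }
  prof <- do.call(rbind, rows)
  if (anyDuplicated(prof$read_id)) {
    warning("duplicate primary records; keeping the first per read id")
    prof <- prof[!duplicated(prof$read_id), , drop = FALSE]
  }
  low <- prof$n_cpg_assessed < max(1L, as.integer(min_cpg))
  prof$label[low] <- "no_cpg"
  prof$methylation_fraction[prof$label == "no_cpg"] <- NA_real_
  rownames(prof) <- NULL
  prof
}

.filter_by_ids <- function(in_bam, out_bam, ids) {
  ids <- unique(ids)
  rules <- S4Vectors::FilterRules(list(by_id = function(x) x$qname %in% ids))
  Rsamtools::filterBam(
    in_bam, out_bam,
    filter = rules,
    param = Rsamtools::ScanBamParam(
      what = "qname",
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE)
    ),
    indexDestination = TRUE
  )
}

#' Partition a modBAM into unmethylated and methylated outputs
#'
#' Screens every mapped primary read and writes each read's records
#' (primary plus any supplementary alignments, which inherit the primary's
#' label) to exactly one output BAM: `out_minus` for reads below the split
#' threshold, `out_plus` for reads at or above it. Unmapped records are
#' excluded; secondary alignments are dropped. Outputs are
#' coordinate-sorted and indexed.
#'
#' @inheritParams screen_bam
#' @param in_bam Input BAM (coordinate-sorted).
#' @param out_minus,out_plus Output BAM paths (must differ).
#' @param no_cpg_policy Where reads without assessable CpGs go:
#'   `"to_minus"` (default; absence of methylation evidence matches the
#'   unmethylated mtDNA class), `"to_plus"`, `"separate_file"` (requires
#'   `out_no_cpg`), or `"drop"`.
#' @param out_no_cpg Output path used by `no_cpg_policy = "separate_file"`.
#' @param report_path Optional path for the per-read profile TSV.
#' @return A `partition_result` object: counts (`n_input`, `n_minus`,
#'   `n_plus`, `n_no_cpg`, `n_unmapped_excluded`), thresholds, output
#'   paths, and the profile table in `$profiles`.
#' @export
split_bam <- function(in_bam, out_minus, out_plus,
                      split_threshold = 0.15, call_threshold = 0.5,
                      no_cpg_policy = c("to_minus", "to_plus",
                                        "separate_file", "drop"),
                      out_no_cpg = NULL, min_cpg = 1L,
                      confidence_band = NULL, report_path = NULL) {
  no_cpg_policy <- match.arg(no_cpg_policy)
  if (!file.exists(in_bam)) {
    ms_stop(paste0("BAM file not found: ", in_bam), "ms_input_error")
  }
  np <- function(p) normalizePath(p, mustWork = FALSE)
  if (np(out_minus) == np(out_plus)) {
    ms_stop("out_minus and out_plus must be different files",
            "ms_config_error")
  }
  if (no_cpg_policy == "separate_file" && is.null(out_no_cpg)) {
    ms_stop("no_cpg_policy = 'separate_file' requires out_no_cpg",
            "ms_config_error")
  }
  prof <- screen_bam(in_bam, call_threshold = call_threshold,
                     split_threshold = split_threshold, min_cpg = min_cpg,
                     confidence_band = confidence_band)
  minus_ids <- prof$read_id[prof$label == "minus_m"]
  plus_ids <- prof$read_id[prof$label == "plus_m"]
  nocpg_ids <- prof$read_id[prof$label == "no_cpg"]

  .filter_by_ids(in_bam, out_minus,
                 c(minus_ids, if (no_cpg_policy == "to_minus") nocpg_ids))
  .filter_by_ids(in_bam, out_plus,
                 c(plus_ids, if (no_cpg_policy == "to_plus") nocpg_ids))
  if (no_cpg_policy == "separate_file") {
    .filter_by_ids(in_bam, out_no_cpg, nocpg_ids)
  }
  n_unmapped <- Rsamtools::countBam(
    in_bam,
    param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE))
  )$records
  if (!is.null(report_path)) {
    write.table(prof, report_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  structure(list(
    n_input = nrow(prof) + n_unmapped,
    n_minus = length(minus_ids),
    n_plus = length(plus_ids),
    n_no_cpg = length(nocpg_ids),
    n_unmapped_excluded = n_unmapped,
    split_threshold = split_threshold,
    call_threshold = call_threshold,
    no_cpg_policy = no_cpg_policy,
    out_minus = out_minus, out_plus = out_plus, out_no_cpg = out_no_cpg,
    profiles = prof
  ), class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("modBAM partition at split threshold", x$split_threshold,
      "(site call threshold", paste0(x$call_threshold, ")\n"))
  cat(sprintf("  input reads:        %d\n", x$n_input))
  cat(sprintf("  minus-m (< %g):     %d -> %s\n",
              x$split_threshold, x$n_minus, x$out_minus))
  cat(sprintf("  plus-m  (>= %g):    %d -> %s\n",
              x$split_threshold, x$n_plus, x$out_plus))
  cat(sprintf("  no CpG (%s): %d\n", x$no_cpg_policy, x$n_no_cpg))
  cat(sprintf("  unmapped excluded:  %d\n", x$n_unmapped_excluded))
  invisible(x)
}
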