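# Synthetic modBAM generator: a toy circular mitochondrial-like reference
# with controlled strand composition, plus aligned reads with valid MM/ML
# tags whose per-read CpG methylation follows a bimodal mtDNA/NuMT mixture.

#' Configuration for the synthetic modBAM generator
#'
#' Defaults emulate human chrM nanopore data: a 16,569 bp circular
#' reference at 44% GC with GC skew -0.35 and AT skew 0.10 (forward
#' strand); 70% mtDNA-class reads whose per-read site-methylation
#' probability follows Beta(1, 50) (mean ~0.02) and 30% NuMT-class reads
#' following Beta(6, 4) (mean 0.6); log-normal read lengths truncated to
#' `[500, reference_length]`; methylated sites draw ML bytes from a high
#' band (200-255, probability >= 0.78) and unmethylated sites from a low
#' band (0-55, probability <= 0.22).
#'
#' @param reference_length Reference length in bp.
#' @param target_gc_percent,target_gc_skew,target_at_skew Composition
#'   targets for the simulated reference (skews must be in `(-1, 1)`).
#' @param n_reads Number of reads to simulate.
#' @param numt_weight Mixture weight of the methylated NuMT class.
#' @param low_mode,high_mode Length-2 `c(shape1, shape2)` Beta parameters
#'   of the per-read site-methylation probability for the mtDNA and NuMT
#'   classes respectively.
#' @param read_length_meanlog,read_length_sdlog Log-normal read-length
#'   parameters (natural-log scale).
#' @param read_length_min,read_length_max Truncation bounds in bp.
#' @param low_band,high_band Length-2 integer ranges of ML bytes drawn for
#'   unmethylated and methylated sites.
#' @param with_hmc Also emit 5hmC (`h`) calls (interleaved `C+hm` runs,
#'   h bytes from the low band), to exercise [strip_modification()].
#' @param reverse_fraction Fraction of reads aligned to the reverse strand.
#' @param seed Integer seed; every draw is reproducible given the config.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(reference_length = 16569L,
                              target_gc_percent = 44,
                              target_gc_skew = -0.35,
                              target_at_skew = 0.10,
                              n_reads = 1000L,
                              numt_weight = 0.30,
                              low_mode = c(1, 50),
                              high_mode = c(6, 4),
                              read_length_meanlog = log(6000),
                              read_length_sdlog = 0.8,
                              read_length_min = 500L,
                              read_length_max = reference_length,
                              low_band = c(0L, 55L),
                              high_band = c(200L, 255L),
                              with_hmc = FALSE,
                              reverse_fraction = 0.5,
                              seed = 1L) {
  cfg <- list(
    reference_length = as.integer(reference_length),
    target_gc_percent = target_gc_percent,
    target_gc_skew = target_gc_skew,
    target_at_skew = target_at_skew,
    n_reads = as.integer(n_reads),
    numt_weight = numt_weight,
    low_mode = as.numeric(low_mode),
    high_mode = as.numeric(high_mode),
    read_length_meanlog = read_length_meanlog,
    read_length_sdlog = read_length_sdlog,
    read_length_min = as.integer(read_length_min),
    read_length_max = as.integer(min(read_length_max, reference_length)),
    low_band = as.integer(low_band),
    high_band = as.integer(high_band),
    with_hmc = isTRUE(with_hmc),
    reverse_fraction = reverse_fraction,
    seed = as.integer(seed)
  )
  if (cfg$reference_length < 2L) {
    ms_stop("reference_length must be at least 2 bp", "ms_config_error")
  }
  if (cfg$numt_weight < 0 || cfg$numt_weight > 1 ||
      cfg$reverse_fraction < 0 || cfg$reverse_fraction > 1) {
    ms_stop("mixture and strand weights must lie in [0, 1]",
            "ms_config_error")
  }
  if (cfg$n_reads < 0L) ms_stop("n_reads must be >= 0", "ms_config_error")
  if (cfg$read_length_min < 2L || cfg$read_length_min > cfg$read_length_max) {
    ms_stop("read length bounds must satisfy 2 <= min <= max",
            "ms_config_error")
  }
  if (any(cfg$low_band < 0L) || any(cfg$high_band > 255L) ||
      cfg$low_band[1] > cfg$low_band[2] || cfg$high_band[1] > cfg$high_band[2]) {
    ms_stop("ML byte bands must be ordered and within 0..255",
            "ms_config_error")
  }
  composition_frequencies(cfg)  # validates feasibility
  structure(cfg, class = "simulation_config")
}

#' Base frequencies satisfying the composition targets
#'
#' Solves the four base frequencies from GC%, GC skew and AT skew plus the
#' sum-to-one constraint: `g = gc (1 + s_gc) / 2`, `c = gc (1 - s_gc) / 2`,
#' `a = (1 - gc)(1 + s_at) / 2`, `t = (1 - gc)(1 - s_at) / 2`.
#'
#' @param config A [simulation_config()] (or any list with the three
#'   `target_*` fields).
#' @return Named numeric vector `c(A, C, G, T)` summing to one.
#' @export
composition_frequencies <- function(config) {
  gc <- config$target_gc_percent / 100
  sg <- config$target_gc_skew
  sa <- config$target_at_skew
  if (gc <= 0 || gc >= 1) {
    ms_stop(sprintf("target_gc_percent = %g violates 0 < GC%% < 100",
                    config$target_gc_percent), "ms_config_error")
  }
  if (abs(sg) >= 1) {
    ms_stop(sprintf("target_gc_skew = %g violates |skew| < 1", sg),
            "ms_config_error")
  }
  if (abs(sa) >= 1) {
    ms_stop(sprintf("target_at_skew = %g violates |skew| < 1", sa),
            "ms_config_error")
  }
  c(A = (1 - gc) * (1 + sa) / 2, C = gc * (1 - sg) / 2,
    G = gc * (1 + sg) / 2, T = (1 - gc) * (1 - sa) / 2)
}

#' Simulate a circular mitochondrial-like reference sequence
#'
#' Draws an i.i.d. sequence whose expected composition solves the GC%, GC
#' skew and AT skew targets simultaneously (see
#' [composition_frequencies()]). Circularity is honoured downstream by
#' letting simulated reads wrap around the origin.
#'
#' @param config A [simulation_config()].
#' @return A single DNA string of length `reference_length`.
#' @export
simulate_reference <- function(config) {
  freqs <- composition_frequencies(config)
  set.seed(config$seed)
  paste(sample(names(freqs), config$reference_length, replace = TRUE,
               prob = freqs), collapse = "")
}

#' Simulate aligned modified-base reads from a reference
#'
#' Each read samples its class (`numt` with probability `numt_weight`,
#' else `mito`), a uniform start on the circular reference, a truncated
#' log-normal length and an alignment strand. Both classes take their
#' sequence from the reference (the high sequence similarity of NuMTs to
#' mtDNA is the point); they differ only in methylation. A per-read
#' site-methylation probability is drawn from the class Beta distribution
#' and every CpG cytosine of the read (as-sequenced orientation) receives
#' a 5mC call with an ML byte from the high band with that probability,
#' else from the low band; explicit-skip (`?`) MM runs are emitted.
#' Reverse-strand records store the reverse-complemented sequence with MM
#' referring to the as-sequenced orientation. Reads that wrap the circular
#' origin are written as a primary plus a supplementary record sharing the
#' read id (soft-clipped halves), exercising the supplementary-label rule.
#'
#' @param reference Reference sequence (string), e.g. from
#'   [simulate_reference()].
#' @param config A [simulation_config()].
#' @param out_bam Output BAM path (coordinate-sorted, indexed).
#' @param truth_path Optional TSV path for the ground-truth table.
#' @param reference_name Reference name written to the header.
#' @return Invisibly, a list with `bam`, `truth` (data frame with
#'   `read_id`, `true_class`, `true_site_methylation`, `n_cpg`,
#'   `read_length`, `is_reverse`, `wraps_origin`) and `truth_path`.
#' @export
simulate_reads <- function(reference, config, out_bam, truth_path = NULL,
                           reference_name = "chrM_sim") {
  L <- nchar(reference)
  n <- config$n_reads
  # separate stream from simulate_reference so the two can be called in
  # either order with identical results
  set.seed((config$seed + 1L) %% .Machine$integer.max)

  header <- c("@HD\tVN:1.6",
              paste0("@SQ\tSN:", reference_name, "\tLN:", L))
  refref <- paste0(reference, reference)

  cls <- character(0); p_true <- numeric(0)
  lines <- character(0)
  truth <- data.frame(
    read_id = character(), true_class = character(),
    true_site_methylation = double(), n_cpg = integer(),
    read_length = integer(), is_reverse = logical(),
    wraps_origin = logical(), stringsAsFactors = FALSE
  )
  if (n > 0L) {
    cls <- ifelse(runif(n) < config$numt_weight, "numt", "mito")
    p_true <- ifelse(
      cls == "numt",
      rbeta(n, config$high_mode[1], config$high_mode[2]),
      rbeta(n, config$low_mode[1], config$low_mode[2])
    )
    lo <- plnorm(config$read_length_min, config$read_length_meanlog,
                 config$read_length_sdlog)
    hi <- plnorm(config$read_length_max, config$read_length_meanlog,
                 config$read_length_sdlog)
    len <- as.integer(pmax(config$read_length_min, pmin(
      config$read_length_max,
      round(qlnorm(runif(n, lo, hi), config$read_length_meanlog,
                   config$read_length_sdlog)))))
    start <- sample.int(L, n, replace = TRUE)
    is_rev <- runif(n) < config$reverse_fraction

    rec_list <- vector("list", n)
    truth_list <- vector("list", n)
    for (i in seq_len(n)) {
      id <- sprintf("read%06d", i)
      slice <- substr(refref, start[i], start[i] + len[i] - 1L)
      molecule <- if (is_rev[i]) revcomp(slice) else slice
      cpg <- cpg_sites(molecule)
      ncpg <- length(cpg)
      tags <- character(0)
      if (ncpg > 0L) {
        meth <- runif(ncpg) < p_true[i]
        hi_b <- sample(config$high_band[1]:config$high_band[2], ncpg,
                       replace = TRUE)
        lo_b <- sample(config$low_band[1]:config$low_band[2], ncpg,
                       replace = TRUE)
        m_bytes <- ifelse(meth, hi_b, lo_b)
        chars <- strsplit(molecule, "", fixed = TRUE)[[1]]
        cpos <- which(chars == "C")
        occ <- match(cpg + 1L, cpos)
        deltas <- diff(c(0L, occ)) - 1L
        if (config$with_hmc) {
          h_bytes <- sample(config$low_band[1]:config$low_band[2], ncpg,
                            replace = TRUE)
          mm <- paste0("C+hm?,", paste(deltas, collapse = ","), ";")
          ml <- as.integer(rbind(h_bytes, m_bytes))
        } else {
          mm <- paste0("C+m?,", paste(deltas, collapse = ","), ";")
          ml <- m_bytes
        }
        tags <- c(paste0("MM:Z:", mm),
                  paste0("ML:B:C,", paste(ml, collapse = ",")))
      }
      qual <- strrep("I", len[i])
      flag1 <- if (is_rev[i]) 16L else 0L
      wraps <- start[i] + len[i] - 1L > L
      if (!wraps) {
        recs <- paste(c(id, flag1, reference_name, start[i], 60L,
                        paste0(len[i], "M"), "*", 0L, 0L, slice, qual, tags),
                      collapse = "\t")
      } else {
        len1 <- L - start[i] + 1L
        len2 <- len[i] - len1
        recs <- c(
          paste(c(id, flag1, reference_name, start[i], 60L,
                  paste0(len1, "M", len2, "S"), "*", 0L, 0L, slice, qual,
                  tags), collapse = "\t"),
          paste(c(id, flag1 + 2048L, reference_name, 1L, 60L,
                  paste0(len1, "S", len2, "M"), "*", 0L, 0L, slice, qual,
                  tags), collapse = "\t")
        )
      }
      rec_list[[i]] <- recs
      truth_list[[i]] <- data.frame(
        read_id = id, true_class = cls[i],
        true_site_methylation = p_true[i], n_cpg = ncpg,
        read_length = len[i], is_reverse = is_rev[i],
        wraps_origin = wraps, stringsAsFactors = FALSE
      )
    }
    lines <- unlist(rec_list, use.names = FALSE)
    truth <- do.call(rbind, truth_list)
  }
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  writeLines(c(header, lines), sam)
  sam_to_bam(sam, out_bam)
  if (!is.null(truth_path)) {
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(list(bam = out_bam, truth = truth, truth_path = truth_path))
}

#' Generate a complete synthetic fixture in one directory
#'
#' Writes `reference.fasta`, `reads.bam` (+ index), `truth.tsv` and
#' `config.json` under `dir`, all derived from one [simulation_config()].
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths, the reference string and
#'   the truth data frame.
#' @export
simulate_fixture <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reference <- simulate_reference(config)
  fasta <- file.path(dir, "reference.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(reference, "chrM_sim")), fasta)
  bam <- file.path(dir, "reads.bam")
  truth_path <- file.path(dir, "truth.tsv")
  sim <- simulate_reads(reference, config, bam, truth_path = truth_path)
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(reference_fasta = fasta, bam = bam,
                 truth_path = truth_path, config_path = cfg_path,
                 reference = reference, truth = sim$truth))
}
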