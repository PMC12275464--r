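# Per-read CpG quantification, classification and BAM partitioning.

test_that("cpg_sites finds the C of every CG dinucleotide", {
  expect_identical(cpg_sites("ACGTCG"), c(1L, 4L))
  expect_identical(cpg_sites("CCCC"), integer())
  expect_identical(cpg_sites("CGCGCG"), c(0L, 2L, 4L))
  expect_identical(cpg_sites("CG"), 0L)
  expect_identical(cpg_sites("G"), integer())
})

test_that("read methylation fraction counts CpG 5mC calls against the threshold", {
  # 10 CpGs, explicit mode, 2 confidently methylated + 8 confidently not
  seq <- strrep("CGA", 10)
  bytes <- as.integer(c(230, 230, rep(10, 8)))
  rec <- list(read_id = "r1", seq = seq,
              mm = paste0("C+m?,", paste(rep(0L, 10), collapse = ","), ";"),
              ml = bytes)
  p <- read_methylation_fraction(rec)
  expect_equal(p$n_cpg_assessed, 10L)
  expect_equal(p$n_methylated, 2L)
  expect_equal(p$methylation_fraction, 0.2)
  expect_equal(p$label, "plus_m")

  # no MM tag -> no_cpg with NA fraction
  p2 <- read_methylation_fraction(list(read_id = "r2", seq = seq, mm = NA))
  expect_equal(p2$n_cpg_assessed, 0L)
  expect_equal(p2$label, "no_cpg")
  expect_true(is.na(p2$methylation_fraction))

  # record without a sequence is an input error
  expect_error(read_methylation_fraction(list(read_id = "r3", seq = "*",
                                              mm = "C+m,0;", ml = 1L)),
               class = "ms_input_error")
})

test_that("implicit-skip runs add uncalled CpGs to the denominator as unmodified", {
  seq <- "CGACGACGACGA"  # 4 CpGs at 0, 3, 6, 9
  # explicit: only the two called sites are assessed
  exp_rec <- list(seq = seq, mm = "C+m?,0,0;", ml = c(230L, 230L))
  expect_equal(read_methylation_fraction(exp_rec)$methylation_fraction, 1)
  # implicit: the two uncalled CpGs count as unmodified
  imp_rec <- list(seq = seq, mm = "C+m.,0,0;", ml = c(230L, 230L))
  p <- read_methylation_fraction(imp_rec)
  expect_equal(p$n_cpg_assessed, 4L)
  expect_equal(p$methylation_fraction, 0.5)
})

test_that("non-CpG 5mC calls are excluded and tallied", {
  seq <- "CACGT"  # C at 0 (non-CpG) and 2 (CpG)
  rec <- list(seq = seq, mm = "C+m?,0,0;", ml = c(230L, 230L))
  p <- read_methylation_fraction(rec)
  expect_equal(p$n_cpg_assessed, 1L)
  expect_equal(p$n_noncpg_calls, 1L)
  expect_equal(p$methylation_fraction, 1)
})

test_that("classification boundary at the threshold goes to plus_m", {
  expect_equal(classify_read(0.1499), "minus_m")
  expect_equal(classify_read(0.15), "plus_m")
  expect_equal(classify_read(0.0), "minus_m")
  expect_equal(classify_read(NA_real_), "no_cpg")
  expect_equal(classify_read(c(0, 0.5, NaN)), c("minus_m", "plus_m", "no_cpg"))
  expect_error(classify_read(0.1, split_threshold = 1.5),
               class = "ms_config_error")
  expect_error(classify_read(0.1, split_threshold = -0.1),
               class = "ms_config_error")
})

fx <- local_sim_fixture(n_reads = 300L, seed = 42L)

test_that("split_bam partitions the mapped reads exactly and reproducibly", {
  d <- fx$dir
  res <- split_bam(fx$bam, file.path(d, "minus.bam"),
                   file.path(d, "plus.bam"),
                   report_path = file.path(d, "prof.tsv"))
  expect_s3_class(res, "partition_result")
  expect_equal(res$n_minus + res$n_plus + res$n_no_cpg +
               res$n_unmapped_excluded, res$n_input)
  expect_equal(res$n_input, 300L)

  ids_in <- unique(scan_modbam(fx$bam)$qname)
  ids_minus <- unique(scan_modbam(file.path(d, "minus.bam"))$qname)
  ids_plus <- unique(scan_modbam(file.path(d, "plus.bam"))$qname)
  expect_length(intersect(ids_minus, ids_plus), 0)
  expect_setequal(c(ids_minus, ids_plus), ids_in)

  # recomputing fractions from each output reproduces the labels
  pm <- screen_bam(file.path(d, "minus.bam"))
  pp <- screen_bam(file.path(d, "plus.bam"))
  expect_true(all(pm$label %in% c("minus_m", "no_cpg")))
  expect_true(all(pp$label == "plus_m"))

  # the per-read report round-trips
  tsv <- read.delim(file.path(d, "prof.tsv"))
  expect_equal(nrow(tsv), 300L)
  expect_setequal(names(tsv),
                  c("read_id", "n_cpg_assessed", "n_methylated",
                    "methylation_fraction", "n_noncpg_calls", "label"))
})

test_that("supplementary records follow their primary's label", {
  # force wrap-around reads: long lengths on a short reference
  wfx <- local_sim_fixture(n_reads = 60L, seed = 9L,
                           reference_length = 4000L,
                           read_length_meanlog = log(3500),
                           read_length_sdlog = 0.1,
                           read_length_min = 3000L)
  expect_gt(sum(wfx$truth$wraps_origin), 5L)
  d <- wfx$dir
  split_bam(wfx$bam, file.path(d, "m.bam"), file.path(d, "p.bam"))
  sm <- scan_modbam(file.path(d, "m.bam"), include_supplementary = TRUE)
  sp <- scan_modbam(file.path(d, "p.bam"), include_supplementary = TRUE)
  expect_true(any(sm$is_supplementary) || any(sp$is_supplementary))
  expect_length(intersect(unique(sm$qname), unique(sp$qname)), 0)
  # every supplementary sits in the same file as its primary
  expect_true(all(sm$qname[sm$is_supplementary] %in%
                  sm$qname[!sm$is_supplementary]))
  expect_true(all(sp$qname[sp$is_supplementary] %in%
                  sp$qname[!sp$is_supplementary]))
})

test_that("thresholds act monotonically on fractions and partition sizes", {
  p1 <- screen_bam(fx$bam, call_threshold = 0.5)
  p2 <- screen_bam(fx$bam, call_threshold = 0.9)
  m <- merge(p1, p2, by = "read_id")
  ok <- !is.na(m$methylation_fraction.x) & !is.na(m$methylation_fraction.y)
  expect_true(all(m$methylation_fraction.y[ok] <=
                  m$methylation_fraction.x[ok]))

  n_minus <- vapply(c(0, 0.15, 0.5, 1), function(thr) {
    sum(classify_read(p1$methylation_fraction, thr) == "minus_m")
  }, numeric(1))
  expect_true(all(diff(n_minus) >= 0))
  # threshold 0: no fraction is below 0
  expect_equal(n_minus[1], 0)
})

test_that("no-CpG reads are routed according to policy", {
  # tiny reference with nearly no CpGs -> some reads have none
  nfx <- local_sim_fixture(n_reads = 40L, seed = 3L,
                           reference_length = 2000L,
                           target_gc_percent = 10,
                           read_length_min = 40L,
                           read_length_meanlog = log(60),
                           read_length_sdlog = 0.2)
  prof <- screen_bam(nfx$bam)
  expect_gt(sum(prof$label == "no_cpg"), 0L)
  d <- nfx$dir
  r1 <- split_bam(nfx$bam, file.path(d, "m1.bam"), file.path(d, "p1.bam"),
                  no_cpg_policy = "to_minus")
  expect_setequal(
    scan_modbam(file.path(d, "m1.bam"))$qname,
    prof$read_id[prof$label %in% c("minus_m", "no_cpg")])
  r2 <- split_bam(nfx$bam, file.path(d, "m2.bam"), file.path(d, "p2.bam"),
                  no_cpg_policy = "drop")
  expect_setequal(
    c(scan_modbam(file.path(d, "m2.bam"))$qname,
      scan_modbam(file.path(d, "p2.bam"))$qname),
    prof$read_id[prof$label != "no_cpg"])
  r3 <- split_bam(nfx$bam, file.path(d, "m3.bam"), file.path(d, "p3.bam"),
                  no_cpg_policy = "separate_file",
                  out_no_cpg = file.path(d, "n3.bam"))
  expect_setequal(scan_modbam(file.path(d, "n3.bam"))$qname,
                  prof$read_id[prof$label == "no_cpg"])
  expect_error(
    split_bam(nfx$bam, file.path(d, "m4.bam"), file.path(d, "p4.bam"),
              no_cpg_policy = "separate_file"),
    class = "ms_config_error")
})

test_that("degenerate split inputs are handled", {
  efx <- local_sim_fixture(n_reads = 0L, seed = 1L)
  d <- efx$dir
  res <- split_bam(efx$bam, file.path(d, "m.bam"), file.path(d, "p.bam"))
  expect_equal(res$n_input, 0L)
  expect_equal(res$n_minus + res$n_plus + res$n_no_cpg, 0L)
  expect_equal(scan_modbam(file.path(d, "m.bam"))$n, 0L)

  expect_error(split_bam(efx$bam, file.path(d, "x.bam"),
                         file.path(d, "x.bam")),
               class = "ms_config_error")
  expect_error(split_bam(file.path(d, "absent.bam"), file.path(d, "a.bam"),
                         file.path(d, "b.bam")),
               class = "ms_input_error")
})
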