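# Independent brute-force oracle for the MM/ML codec, plus fuzzing helpers.
# The oracle walks the read base by base with an explicit pointer, never
# touching the package's vectorised enumeration path.

oracle_decode <- function(seq, mm, ml) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  items <- strsplit(mm, ";", fixed = TRUE)[[1]]
  rows <- list()
  off <- 0L
  for (item in items) {
    base <- substr(item, 1, 1)
    head_rest <- substring(item, 3)
    body <- strsplit(head_rest, ",", fixed = TRUE)[[1]]
    codestr <- sub("[.?]$", "", body[1])
    codes <- if (grepl("^[0-9]+$", codestr)) codestr
             else strsplit(codestr, "", fixed = TRUE)[[1]]
    deltas <- if (length(body) > 1) as.integer(body[-1]) else integer()
    ptr <- 0L
    for (dlt in deltas) {
      skipped <- -1L
      repeat {
        ptr <- ptr + 1L
        if (ptr > length(chars)) stop("oracle: delta overruns sequence")
        if (base == "N" || chars[ptr] == base) {
          skipped <- skipped + 1L
          if (skipped == dlt) break
        }
      }
      for (code in codes) {
        off <- off + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          position = ptr - 1L, mod_code = code, ml_byte = ml[off],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(position = integer(), mod_code = character(),
                      ml_byte = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# A random valid (seq, mm, ml) triple with 1-2 runs.
random_mod_read <- function(max_len = 60L) {
  len <- sample(5:max_len, 1)
  seq <- random_dna(len)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_runs <- sample(1:2, 1)
  items <- character(0)
  ml <- integer(0)
  used <- character(0)
  for (r in seq_len(n_runs)) {
    repeat {
      base <- sample(c("A", "C", "G", "T", "N"), 1)
      strand <- sample(c("+", "-"), 1)
      codes <- sample(list("m", "h", c("h", "m"), "76792"), 1)[[1]]
      key <- paste(base, strand, paste(codes, collapse = ""))
      if (!key %in% used) break
    }
    used <- c(used, key)
    flag <- sample(c("?", ".", ""), 1)
    n_occ <- if (base == "N") length(chars) else sum(chars == base)
    k <- if (n_occ == 0) 0L else sample(0:min(n_occ, 8L), 1)
    dstr <- ""
    if (k > 0) {
      occ <- sort(sample(n_occ, k))
      deltas <- diff(c(0L, occ)) - 1L
      dstr <- paste0(",", paste(deltas, collapse = ","))
      ml <- c(ml, sample(0:255, k * length(codes), replace = TRUE))
    }
    items <- c(items,
               paste0(base, strand, paste(codes, collapse = ""), flag, dstr,
                      ";"))
  }
  list(seq = seq, mm = paste(items, collapse = ""), ml = ml)
}

# Small simulated fixture shared by several unit-test files.
local_sim_fixture <- function(n_reads = 300L, seed = 42L, dir = NULL, ...) {
  dir <- dir %||% withr::local_tempdir(.local_envir = parent.frame())
  cfg <- mitosieve::simulation_config(n_reads = n_reads, seed = seed, ...)
  fx <- mitosieve::simulate_fixture(cfg, dir)
  fx$config <- cfg
  fx$dir <- dir
  fx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
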