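# MM/ML modified-base tag codec.
#
# An MM tag is a semicolon-separated list of "runs", each of the form
#   <base><strand><codes>[.?][,delta]* ;
# e.g. "C+m?,1,0;".  Deltas count skipped occurrences of <base> along the
# read in its AS-SEQUENCED orientation; for records aligned to the reverse
# strand the stored SEQ must be reverse-complemented before decoding.  The
# ML tag carries one byte per (call position x code), interleaved per
# position for multi-code runs such as "C+hm".

.mm_run_re <- "^([ACGTUN])([+-])([a-zA-Z]+|[0-9]+)([.?]?)((?:,[0-9]+)*)$"

.empty_calls <- function() {
  data.frame(
    position = integer(), canonical_base = character(),
    mod_strand = character(), mod_code = character(),
    ml_byte = integer(), probability = double(), run = integer(),
    stringsAsFactors = FALSE
  )
}

.empty_runs <- function() {
  out <- data.frame(
    canonical_base = character(), mod_strand = character(),
    mod_codes = character(), flag = character(), skip_mode = character(),
    n_calls = integer(), stringsAsFactors = FALSE
  )
  out$deltas <- list()
  out
}

.split_codes <- function(codestr) {
  if (grepl("^[0-9]+$", codestr)) codestr
  else strsplit(codestr, "", fixed = TRUE)[[1]]
}

#' Decode MM/ML tags into explicit per-position modification calls
#'
#' Resolves the delta-encoded MM positions against the read sequence and
#' pairs each call with its ML probability byte.  Multi-code runs (e.g.
#' `C+hm`) consume ML bytes interleaved per position, and both the
#' explicit-skip (`?`) and implicit-skip (`.` or absent) dialects are
#' preserved in the returned run table.
#'
#' @param read_seq The read sequence in its as-sequenced orientation (for
#'   reverse-strand alignments, reverse-complement the stored SEQ first).
#' @param mm The MM tag value, e.g. `"C+m?,1,0;"`. `NA`, `NULL` or `""`
#'   yields zero calls.
#' @param ml Integer vector of ML bytes (0..255), or `NULL`. A missing ML
#'   with a non-empty MM is accepted with a warning and probability 1.0.
#' @param read_id Optional read name used in error messages.
#' @return A list with two data frames: `calls` (columns `position`
#'   (0-based, as-sequenced), `canonical_base`, `mod_strand`, `mod_code`,
#'   `ml_byte`, `probability`, `run`) and `runs` (one row per MM run:
#'   `canonical_base`, `mod_strand`, `mod_codes`, `flag`, `skip_mode`,
#'   `n_calls`, `deltas`).
#' @examples
#' decode_mod_tags("AGCTCCG", "C+m,1,0;", c(230L, 10L))$calls
#' @export
decode_mod_tags <- function(read_seq, mm, ml = NULL, read_id = NULL) {
  stopifnot(is.character(read_seq), length(read_seq) == 1L, !is.na(read_seq))
  id <- read_id %||% "<unnamed read>"
  if (is.null(mm) || length(mm) != 1L || is.na(mm) || !nzchar(mm)) {
    return(list(calls = .empty_calls(), runs = .empty_runs()))
  }
  if (!is.null(ml)) ml <- as.integer(ml)

  items <- strsplit(mm, ";", fixed = TRUE)[[1]]
  chars <- strsplit(read_seq, "", fixed = TRUE)[[1]]

  run_rows <- vector("list", length(items))
  call_rows <- vector("list", length(items))
  n_bytes <- 0L
  for (k in seq_along(items)) {
    item <- items[[k]]
    parts <- regmatches(item, regexec(.mm_run_re, item))[[1]]
    if (!length(parts)) {
      ms_stop(sprintf("malformed MM run '%s' in read %s", item, id),
              "ms_parse_error")
    }
    base <- parts[2]; strand <- parts[3]
    codes <- .split_codes(parts[4])
    flagchr <- parts[5]
    deltas <- if (nzchar(parts[6])) {
      as.integer(strsplit(sub("^,", "", parts[6]), ",", fixed = TRUE)[[1]])
    } else {
      integer()
    }
    basepos <- if (base == "N") seq_along(chars) else which(chars == base)
    idx <- cumsum(deltas + 1L)
    if (length(idx) && idx[length(idx)] > length(basepos)) {
      ms_stop(sprintf(
        paste0("MM run '%s' of read %s skips past the last %s ",
               "(%d occurrences in a %d bp read)"),
        item, id, base, length(basepos), length(chars)), "ms_coord_error")
    }
    pos0 <- basepos[idx] - 1L
    ncode <- length(codes)
    ncall <- length(pos0) * ncode
    if (ncall > 0L) {
      bytes <- if (is.null(ml)) rep(NA_integer_, ncall)
               else ml[n_bytes + seq_len(ncall)]
      call_rows[[k]] <- data.frame(
        position = rep(pos0, each = ncode),
        canonical_base = base, mod_strand = strand,
        mod_code = rep(codes, times = length(pos0)),
        ml_byte = bytes,
        probability = if (is.null(ml)) 1.0 else ml_byte_to_prob(bytes),
        run = k, stringsAsFactors = FALSE
      )
    }
    n_bytes <- n_bytes + ncall
    rr <- data.frame(
      canonical_base = base, mod_strand = strand,
      mod_codes = paste(codes, collapse = ""), flag = flagchr,
      skip_mode = if (identical(flagchr, "?")) "explicit" else "implicit",
      n_calls = ncall, stringsAsFactors = FALSE
    )
    rr$deltas <- list(deltas)
    run_rows[[k]] <- rr
  }
  if (!is.null(ml) && length(ml) != n_bytes) {
    ms_stop(sprintf(
      "ML tag of read %s has %d bytes but MM implies %d calls",
      id, length(ml), n_bytes), "ms_tag_error")
  }
  if (is.null(ml) && n_bytes > 0L) {
    warning(sprintf(
      "read %s carries MM but no ML tag; assuming probability 1.0", id))
  }
  keep <- !vapply(call_rows, is.null, logical(1))
  calls <- if (any(keep)) do.call(rbind, call_rows[keep]) else .empty_calls()
  list(calls = calls, runs = do.call(rbind, run_rows))
}

#' Re-encode modification calls into MM/ML tag values
#'
#' Inverse of [decode_mod_tags()]: rebuilds the delta-encoded MM string and
#' the interleaved ML byte vector from a call table and its run structure,
#' so that `decode(encode(x))` reproduces `x` exactly (positions, codes,
#' bytes, skip-mode flags; header-only runs are preserved).
#'
#' @param calls Data frame of calls as returned by [decode_mod_tags()];
#'   the `run` column assigns each call to a row of `runs`.
#' @param runs Run table as returned by [decode_mod_tags()].
#' @param read_seq Read sequence in as-sequenced orientation.
#' @return A list with elements `mm` (string, `""` when there are no runs)
#'   and `ml` (integer vector, or `NULL` when no call carries a byte).
#' @export
encode_mod_tags <- function(calls, runs, read_seq) {
  if (is.null(runs) || nrow(runs) == 0L) return(list(mm = "", ml = NULL))
  chars <- strsplit(read_seq, "", fixed = TRUE)[[1]]
  items <- character(nrow(runs))
  ml_parts <- vector("list", nrow(runs))
  for (k in seq_len(nrow(runs))) {
    base <- runs$canonical_base[k]
    strand <- runs$mod_strand[k]
    codes <- .split_codes(runs$mod_codes[k])
    rcalls <- calls[calls$run == k, , drop = FALSE]
    upos <- sort(unique(rcalls$position))
    dstr <- ""
    if (length(upos)) {
      if (base != "N" && any(chars[upos + 1L] != base)) {
        bad <- upos[which(chars[upos + 1L] != base)[1]]
        ms_stop(sprintf(
          "call at position %d does not sit on a %s (read base '%s')",
          bad, base, chars[bad + 1L]), "ms_encode_error")
      }
      basepos <- if (base == "N") seq_along(chars) else which(chars == base)
      occ <- match(upos + 1L, basepos)
      deltas <- diff(c(0L, occ)) - 1L
      key <- paste(rcalls$position, rcalls$mod_code)
      want <- paste(rep(upos, each = length(codes)),
                    rep(codes, times = length(upos)))
      bidx <- match(want, key)
      if (anyNA(bidx)) {
        ms_stop("calls are inconsistent with their run's code list",
                "ms_encode_error")
      }
      ml_parts[[k]] <- rcalls$ml_byte[bidx]
      dstr <- paste0(",", paste(deltas, collapse = ","))
    }
    items[k] <- paste0(base, strand, runs$mod_codes[k], runs$flag[k], dstr, ";")
  }
  ml <- unlist(ml_parts, use.names = FALSE)
  ml <- if (length(ml) == 0L || all(is.na(ml))) NULL else as.integer(ml)
  list(mm = paste(items, collapse = ""), ml = ml)
}

#' Remove selected modification codes from a record's MM/ML tags
#'
#' Mirrors the pipeline step that discards 5hmC calls before CpG screening,
#' leaving only 5mC. Under `"drop"` the removed codes' probability mass is
#' discarded (implicitly reassigned to the canonical base) and retained
#' codes keep their positions and bytes untouched. Under `"merge_into_m"`
#' the removed codes' probability mass is added to the 5mC call at the same
#' position (creating one where only the removed code was called), capped
#' at 511/512; on byte scale the merged byte is `min(255, b_m + b_removed)`.
#'
#' @param record A list with elements `seq` (as-sequenced sequence), `mm`,
#'   `ml`, and optionally `read_id`.
#' @param codes_to_remove Character vector of modification codes, e.g. `"h"`.
#' @param policy `"drop"` (default) or `"merge_into_m"`.
#' @return The record with rewritten `mm`/`ml`; records without MM pass
#'   through unchanged.
#' @export
strip_modification <- function(record, codes_to_remove,
                               policy = c("drop", "merge_into_m")) {
  policy <- match.arg(policy)
  if (is.null(record$mm) || is.na(record$mm) || !nzchar(record$mm)) {
    return(record)
  }
  codes_to_remove <- as.character(codes_to_remove)
  dec <- decode_mod_tags(record$seq, record$mm, record$ml,
                         read_id = record$read_id)
  calls <- dec$calls
  runs <- dec$runs

  if (policy == "drop") {
    new_runs <- list(); new_calls <- list(); j <- 0L
    for (k in seq_len(nrow(runs))) {
      keep <- setdiff(.split_codes(runs$mod_codes[k]), codes_to_remove)
      if (!length(keep)) next
      j <- j + 1L
      rr <- runs[k, , drop = FALSE]
      rr$mod_codes <- paste(keep, collapse = "")
      rc <- calls[calls$run == k & calls$mod_code %in% keep, , drop = FALSE]
      if (nrow(rc)) rc$run <- j
      rr$n_calls <- nrow(rc)
      new_runs[[j]] <- rr
      new_calls[[j]] <- rc
    }
    if (!length(new_runs)) {
      record$mm <- ""; record$ml <- NULL
      return(record)
    }
    enc <- encode_mod_tags(do.call(rbind, new_calls),
                           do.call(rbind, new_runs), record$seq)
  } else {
    rem <- calls[calls$mod_code %in% codes_to_remove, , drop = FALSE]
    kept <- calls[!(calls$mod_code %in% codes_to_remove), , drop = FALSE]
    if (nrow(rem)) {
      grp <- paste(rem$canonical_base, rem$mod_strand)
      for (g in unique(grp)) {
        r <- rem[grp == g, , drop = FALSE]
        # sum removed bytes per position (h-only positions become new m calls)
        add <- tapply(r$ml_byte, r$position, function(b) sum(as.numeric(b)))
        add_pos <- as.integer(names(add))
        is_m <- kept$mod_code == "m" &
          paste(kept$canonical_base, kept$mod_strand) == g
        hit <- is_m & kept$position %in% add_pos
        if (any(hit)) {
          extra <- add[as.character(kept$position[hit])]
          kept$ml_byte[hit] <- as.integer(pmin(255, kept$ml_byte[hit] + extra))
        }
        new_pos <- setdiff(add_pos, kept$position[is_m])
        if (length(new_pos)) {
          kept <- rbind(kept, data.frame(
            position = new_pos,
            canonical_base = r$canonical_base[1],
            mod_strand = r$mod_strand[1],
            mod_code = "m",
            ml_byte = as.integer(pmin(255, add[as.character(new_pos)])),
            probability = NA_real_, run = NA_integer_,
            stringsAsFactors = FALSE
          ))
        }
      }
    }
    if (!nrow(kept)) {
      record$mm <- ""; record$ml <- NULL
      return(record)
    }
    # rebuild one run per (base, strand, code), preserving the skip flag of
    # the first original run for that base/strand
    key3 <- paste(kept$canonical_base, kept$mod_strand, kept$mod_code)
    ukey <- unique(key3)
    runs2 <- .empty_runs()
    for (u in ukey) {
      kc <- kept[key3 == u, , drop = FALSE][1, ]
      src <- runs[runs$canonical_base == kc$canonical_base &
                  runs$mod_strand == kc$mod_strand, , drop = FALSE]
      rr <- data.frame(
        canonical_base = kc$canonical_base, mod_strand = kc$mod_strand,
        mod_codes = kc$mod_code,
        flag = if (nrow(src)) src$flag[1] else "?",
        skip_mode = if (nrow(src)) src$skip_mode[1] else "explicit",
        n_calls = sum(key3 == u), stringsAsFactors = FALSE
      )
      rr$deltas <- list(integer())
      runs2 <- rbind(runs2, rr)
    }
    kept$run <- match(key3, ukey)
    kept$probability <- ml_byte_to_prob(kept$ml_byte)
    kept <- kept[order(kept$run, kept$position), , drop = FALSE]
    enc <- encode_mod_tags(kept, runs2, record$seq)
  }
  record$mm <- enc$mm
  record$ml <- enc$ml
  record
}
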