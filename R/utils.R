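# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so the CLI can map failures onto exit codes.
ms_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "ms_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Reverse-complement DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] used to
#' move between the aligned orientation (stored SEQ) and the as-sequenced
#' orientation that MM/ML positions refer to.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert between ML probability bytes and probabilities
#'
#' An ML byte `b` encodes the probability interval `[b/256, (b+1)/256)`;
#' calls are assigned the interval midpoint `(2b + 1)/512`, so probabilities
#' lie in `[1/512, 511/512]`. `prob_to_ml_byte()` is the exact inverse on
#' midpoints: `floor((512 p - 1)/2)`, clamped to 0..255.
#'
#' @param b Integer vector of ML bytes (0..255).
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @return Numeric probabilities, or integer bytes, respectively.
#' @export
ml_byte_to_prob <- function(b) (2 * as.numeric(b) + 1) / 512

#' @rdname ml_byte_to_prob
#' @export
prob_to_ml_byte <- function(p) {
  as.integer(pmax(0, pmin(255, floor((512 * p - 1) / 2))))
}

# Reference-consuming width of CIGAR strings (ops M, D, N, =, X).
cigar_ref_width <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  vapply(ops, function(o) {
    if (!length(o)) return(0L)
    n <- as.integer(sub(".$", "", o))
    op <- substr(o, nchar(o), nchar(o))
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

# SAM text -> sorted, indexed BAM at `bam` (Rsamtools appends ".bam").
sam_to_bam <- function(sam, bam) {
  dest <- sub("\\.bam$", "", bam)
  Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
}
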