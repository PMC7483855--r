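#' Run-length encoding of DNA sequences
#'
#' Noisy long nanopore-like reads mis-measure homopolymer lengths far more
#' often than they mis-call bases. Collapsing each run of identical bases to
#' a single base plus a repeat count makes downstream alignment insensitive
#' to that dominant error mode, so the whole assembly pipeline operates on
#' run-length encoded (RLE) sequence and only re-expands repeat counts at
#' the very end.
#'
#' An `rle_seq` holds `bases`, a string over ACGT in which no two adjacent
#' characters are equal, and `counts`, one repeat count per base, each in
#' 1..255. Reads containing a run longer than 255 are rejected at ingest
#' (callers discard such reads); lowercase input is uppercased, and any
#' other symbol (including ambiguity codes such as N) is invalid.
#'
#' @param raw A single DNA string (ACGT, case-insensitive).
#' @return `rle_encode()` returns an object of class `rle_seq` with fields
#'   `bases` (string) and `counts` (integer vector).
#' @examples
#' x <- rle_encode("GATTTACCA")
#' x$bases          # "GATACA"
#' x$counts         # 1 1 3 1 2 1
#' rle_decode(x)    # "GATTTACCA"
#' @export
rle_encode <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || nchar(raw) == 0L)
    stop_invalid("input must be a single nonempty DNA string")
  raw <- toupper(raw)
  codes <- dna_to_int(raw)
  if (anyNA(codes))
    stop_rejected("sequence contains non-ACGT symbols")
  r <- rle(codes)
  if (any(r$lengths > 255L))
    stop_rejected("sequence contains a homopolymer run longer than 255")
  new_rle_seq(int_to_dna(r$values), as.integer(r$lengths))
}

#' @noRd
new_rle_seq <- function(bases, counts) {
  structure(list(bases = bases, counts = counts), class = "rle_seq")
}

#' @param rle An `rle_seq` object.
#' @rdname rle_encode
#' @export
rle_decode <- function(rle) {
  validate_rle_seq(rle)
  chars <- strsplit(rle$bases, "", fixed = TRUE)[[1L]]
  paste0(strrep(chars, rle$counts), collapse = "")
}

#' @noRd
validate_rle_seq <- function(x) {
  if (!inherits(x, "rle_seq")) stop_invalid("not an rle_seq")
  codes <- dna_to_int(x$bases)
  n <- length(codes)
  if (n != length(x$counts)) stop_invalid("bases/counts length mismatch")
  if (anyNA(codes)) stop_invalid("rle_seq bases must be ACGT")
  if (n > 1L && any(codes[-1L] == codes[-n]))
    stop_invalid("corrupt rle_seq: adjacent equal bases")
  if (any(x$counts < 1L))
    stop_invalid("corrupt rle_seq: counts must be >= 1")
  invisible(x)
}

#' @export
print.rle_seq <- function(x, ...) {
  cat("rle_seq: ", x$bases, "\n        ",
      paste0(ifelse(x$counts > 9L, paste0("(", x$counts, ")"), x$counts),
             collapse = ""), "\n", sep = "")
  invisible(x)
}

#' @export
length.rle_seq <- function(x) nchar(x$bases)

#' Fraction of raw length retained after run-length encoding
#'
#' For long i.i.d. uniform random sequence the expected ratio is 3/4:
#' each position after the first starts a new run with probability 3/4.
#'
#' @inheritParams rle_encode
#' @return Numeric in (0, 1]: RLE length divided by raw length.
#' @export
rle_compression_ratio <- function(raw) {
  x <- rle_encode(raw)
  nchar(x$bases) / nchar(raw)
}

#' Reverse complement of a run-length encoded sequence
#' @param x An `rle_seq`.
#' @return An `rle_seq` of the reverse complement.
#' @export
rle_revcomp <- function(x) {
  new_rle_seq(revcomp(x$bases), rev(x$counts))
}
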