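.BASES <- c("A", "C", "G", "T")

.BASE_CODE <- local({
  m <- rep(NA_integer_, 256)
  m[utf8ToInt("A") + 1L] <- 0L
  m[utf8ToInt("C") + 1L] <- 1L
  m[utf8ToInt("G") + 1L] <- 2L
  m[utf8ToInt("T") + 1L] <- 3L
  m
})

.CODE_BYTE <- as.raw(utf8ToInt("A") * 0 + c(65L, 67L, 71L, 84L))

#' Convert a DNA string to integer codes 0..3 (A,C,G,T); NA for other symbols
#' @noRd
dna_to_int <- function(s) {
  .BASE_CODE[as.integer(charToRaw(s)) + 1L]
}

#' @noRd
int_to_dna <- function(x) {
  rawToChar(.CODE_BYTE[x + 1L])
}

#' Reverse complement of a plain DNA string (uppercase ACGT)
#' @noRd
revcomp <- function(s) {
  int_to_dna(rev(3L - dna_to_int(s)))
}

#' Derive a stage-specific RNG seed from a master seed (stays below 2^31)
#' @noRd
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + stage * 1664525 + 12345) %%
               2147483647)
}

#' Evaluate code with a local RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Signal that a read must be rejected at ingest
#' @noRd
stop_rejected <- function(msg) {
  stop(structure(class = c("nanoasm_read_rejected", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Signal invalid input
#' @noRd
stop_invalid <- function(msg) {
  stop(structure(class = c("nanoasm_invalid_input", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
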