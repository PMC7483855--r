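#' Marker k-mers in run-length space
#'
#' Reads are summarised as the ordered occurrences of a fixed random subset
#' of RLE k-mers ("markers"). Because adjacent bases in RLE sequence are
#' always distinct, there are `4 * 3^(k-1)` valid RLE k-mers of length k.
#' The subset is closed under reverse complement so that the marker
#' representation of a reverse-complemented read can be derived from the
#' forward one, which keeps all downstream steps strand-symmetric.
#'
#' @param k k-mer length (default 10).
#' @return `count_rle_kmers()` returns `4 * 3^(k-1)`.
#' @export
count_rle_kmers <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop_invalid("k must be a positive integer")
  4 * 3^(k - 1)
}

#' Enumerate every RLE-valid k-mer (no two adjacent equal bases)
#' @param k k-mer length; enumeration is exponential, intended for k <= 12.
#' @return Character vector of all valid k-mers, sorted.
#' @export
enumerate_rle_kmers <- function(k) {
  stopifnot(k >= 1, k <= 12)
  kmers <- .BASES
  if (k > 1) {
    for (i in 2:k) {
      last <- substr(kmers, i - 1L, i - 1L)
      kmers <- unlist(lapply(.BASES, function(b) paste0(kmers[last != b], b)))
    }
  }
  sort(kmers)
}

#' @noRd
revcomp_kmers <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Construct a marker set from an explicit member list
#'
#' @param members Character vector of RLE-valid k-mers, closed under
#'   reverse complement.
#' @param ids Optional integer ids, parallel to `members`. Defaults to
#'   dense 0-based ids in lexicographic member order.
#' @param probability,seed Optional metadata recording how the set was
#'   drawn (see [select_markers()]).
#' @param check_rc Require closure under reverse complement (default TRUE;
#'   disable only for illustrative hand-built sets).
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(members, ids = NULL, probability = NA_real_,
                       seed = NA_integer_, check_rc = TRUE) {
  if (anyDuplicated(members)) stop_invalid("duplicate marker k-mers")
  k <- unique(nchar(members))
  if (length(k) != 1L) stop_invalid("marker k-mers must share one length")
  codes_all <- dna_to_int(paste(members, collapse = ""))
  if (anyNA(codes_all)) stop_invalid("marker k-mers must be ACGT")
  mat <- matrix(codes_all, nrow = k)
  if (k > 1L && any(mat[-1L, , drop = FALSE] == mat[-k, , drop = FALSE]))
    stop_invalid("marker k-mers must be RLE-valid (no adjacent equal bases)")
  rc <- revcomp_kmers(members)
  if (check_rc && !all(rc %in% members))
    stop_invalid("marker set must be closed under reverse complement")
  if (is.null(ids)) {
    o <- order(members)
    members <- members[o]
    mat <- mat[, o, drop = FALSE]
    rc <- rc[o]
    ids <- seq_along(members) - 1L
  } else {
    if (anyDuplicated(ids)) stop_invalid("duplicate marker ids")
    ids <- as.integer(ids)
  }
  codes <- as.numeric(colSums(mat * 4^((k - 1):0)))
  tab <- rep(NA_integer_, 4^k)
  tab[codes + 1] <- ids
  rc_of_id <- ids[match(rc, members)]
  structure(list(k = as.integer(k), probability = probability,
                 seed = seed, members = members, ids = ids,
                 code_table = tab, rc_of_id = rc_of_id),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker_set: k=", x$k, ", ", length(x$members), " members",
      if (!is.na(x$probability)) paste0(", probability=", x$probability),
      if (!is.na(x$seed)) paste0(", seed=", x$seed), "\n", sep = "")
  invisible(x)
}

#' Randomly select the marker subset
#'
#' Each reverse-complement pair of RLE-valid k-mers is drawn jointly with
#' the given probability (palindromic k-mers, possible only for even k in
#' RLE space, are drawn singly), so the set is closed under reverse
#' complement by construction. Selection is deterministic given the seed.
#' With defaults k = 10 and probability = 0.1 the expected set size is
#' 0.1 * 4 * 3^9, about 7,900 markers.
#'
#' @param k k-mer length (default 10).
#' @param probability Per-k-mer selection probability (default 0.1).
#' @param seed Integer RNG seed.
#' @return A `marker_set`.
#' @export
select_markers <- function(k = 10, probability = 0.1, seed = 1) {
  if (probability <= 0 || probability > 1)
    stop_invalid("probability must be in (0, 1]")
  all_kmers <- enumerate_rle_kmers(k)
  rc <- revcomp_kmers(all_kmers)
  canon <- sort(unique(pmin(all_kmers, rc)))
  sel <- with_seed(seed, runif(length(canon)) < probability)
  chosen <- canon[sel]
  members <- sort(unique(c(chosen, revcomp_kmers(chosen))))
  marker_set(members, probability = probability, seed = as.integer(seed))
}

#' Locate marker occurrences in an RLE sequence
#'
#' Marker identity lives purely in RLE base space: repeat counts are
#' ignored. Markers may overlap.
#'
#' @param rle An `rle_seq` (or a plain RLE base string).
#' @param ms A `marker_set`.
#' @return An object of class `marker_seq`: list with `ids` (integer
#'   marker ids in left-to-right order), `pos` (1-based RLE start
#'   positions, strictly increasing) and `n_rle` (RLE length scanned).
#' @export
find_markers <- function(rle, ms) {
  bases <- if (inherits(rle, "rle_seq")) rle$bases else rle
  codes <- dna_to_int(bases)
  n <- length(codes)
  if (n < ms$k)
    return(new_marker_seq(integer(0), integer(0), n))
  w <- .kmer_codes(codes, ms$k)
  id <- ms$code_table[w + 1]
  hit <- which(!is.na(id))
  new_marker_seq(id[hit], hit, n)
}

#' @noRd
new_marker_seq <- function(ids, pos, n_rle) {
  structure(list(ids = as.integer(ids), pos = as.integer(pos),
                 n_rle = as.integer(n_rle)), class = "marker_seq")
}

#' @export
length.marker_seq <- function(x) length(x$ids)

#' Marker representation of the reverse-complemented sequence
#'
#' Derived from the forward representation: ids are complemented through
#' the marker set's reverse-complement pairing, order is reversed, and
#' positions are mirrored.
#'
#' @param mseq A `marker_seq` from [find_markers()].
#' @param ms The `marker_set` used to produce it.
#' @return A `marker_seq` for the reverse complement.
#' @export
marker_seq_revcomp <- function(mseq, ms) {
  ids <- rev(ms$rc_of_id[match(mseq$ids, ms$ids)])
  pos <- rev(mseq$n_rle - (mseq$pos + ms$k - 1L) + 1L)
  new_marker_seq(ids, pos, mseq$n_rle)
}

#' Write / read a marker set as a small text file
#'
#' Stores k, selection probability, seed and the member list so an
#' assembly can be reproduced exactly.
#'
#' @param ms A `marker_set`.
#' @param path File path.
#' @export
write_marker_set <- function(ms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#k\t", ms$k),
               paste0("#probability\t", format(ms$probability, digits = 17)),
               paste0("#seed\t", ms$seed),
               paste0(ms$members, "\t", ms$ids)), con)
  invisible(path)
}

#' @rdname write_marker_set
#' @export
read_marker_set <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- strsplit(sub("^#", "", lines[hdr]), "\t")
  meta <- setNames(vapply(meta, `[`, "", 2L), vapply(meta, `[`, "", 1L))
  body <- strsplit(lines[!hdr], "\t")
  marker_set(vapply(body, `[`, "", 1L),
             ids = as.integer(vapply(body, `[`, "", 2L)),
             probability = as.numeric(meta[["probability"]]),
             seed = as.integer(meta[["seed"]]))
}
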