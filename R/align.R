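#' Parameters for marker-space alignment
#'
#' Alignments between oriented reads are computed directly in marker
#' representation: the sequences are ~10x shorter than RLE and use a large
#' alphabet, so an optimal chain of matching markers can be found quickly.
#' Banding heuristics bound how many markers an alignment may skip
#' internally (`max_skip`) and at either end (`max_trim`); marker k-mers
#' occurring too often within either read are excluded beforehand
#' (`max_marker_frequency`). Alignments with fewer than
#' `min_aligned_marker_count` aligned markers are rejected.
#'
#' @param max_skip Maximum markers skipped between consecutive aligned
#'   markers, per read (default 30).
#' @param max_trim Maximum unaligned markers at each end, taken as the
#'   minimum over the two reads (default 30).
#' @param max_marker_frequency Exclude markers occurring more than this
#'   many times in either read (default 10).
#' @param min_aligned_marker_count Minimum aligned markers for an
#'   alignment to be accepted (default 40).
#' @return An `align_params` list.
#' @export
align_params <- function(max_skip = 30L, max_trim = 30L,
                         max_marker_frequency = 10L,
                         min_aligned_marker_count = 40L) {
  stopifnot(max_skip >= 1, max_trim >= 0, max_marker_frequency >= 1,
            min_aligned_marker_count >= 1)
  structure(list(max_skip = as.integer(max_skip),
                 max_trim = as.integer(max_trim),
                 max_marker_frequency = as.integer(max_marker_frequency),
                 min_aligned_marker_count = as.integer(min_aligned_marker_count)),
            class = "align_params")
}

#' Exclude markers that are too frequent within either read
#'
#' @param a_ids,b_ids Integer marker-id vectors.
#' @param max_marker_frequency Occurrence threshold (absolute, per read).
#' @return List with `a_keep`, `b_keep`: indices of retained positions.
#' @export
filter_frequent_markers <- function(a_ids, b_ids, max_marker_frequency) {
  ta <- table(a_ids); tb <- table(b_ids)
  bad <- unique(c(as.integer(names(ta)[ta > max_marker_frequency]),
                  as.integer(names(tb)[tb > max_marker_frequency])))
  list(a_keep = which(!(a_ids %in% bad)), b_keep = which(!(b_ids %in% bad)))
}

#' Banded optimal alignment of two marker sequences
#'
#' Maximises the number of aligned markers subject to the skip and trim
#' bounds (applied per read, in the frequency-filtered coordinate space).
#' Ties are broken by smaller total skip, then by the lexicographically
#' earliest chain. Returns a rejection (`accepted = FALSE`) rather than an
#' error when fewer than `min_aligned_marker_count` markers align.
#'
#' @param a,b `marker_seq` objects (or integer id vectors) from the same
#'   marker set.
#' @param params An [align_params()] list.
#' @return Object of class `marker_alignment`: `accepted`, `pairs`
#'   (two-column matrix of 1-based ordinals into the original sequences),
#'   `aligned_count`, `total_skip`, `max_skip_seen`, `trim_a`, `trim_b`
#'   (left/right unaligned marker counts, filtered space), and
#'   `contained_a`/`contained_b` flags.
#' @export
align_markers <- function(a, b, params = align_params()) {
  a_ids <- if (inherits(a, "marker_seq")) a$ids else as.integer(a)
  b_ids <- if (inherits(b, "marker_seq")) b$ids else as.integer(b)
  f <- filter_frequent_markers(a_ids, b_ids, params$max_marker_frequency)
  fa <- a_ids[f$a_keep]; fb <- b_ids[f$b_keep]
  res <- .chain_align(fa, fb, params$max_skip, params$max_trim)
  na <- length(fa); nb <- length(fb)
  if (res$count == 0L)
    return(structure(list(accepted = FALSE, aligned_count = 0L,
                          pairs = matrix(integer(0), 0, 2)),
                     class = "marker_alignment"))
  p <- res$pairs
  trim_a <- c(p[1L, 1L] - 1L, na - p[res$count, 1L])
  trim_b <- c(p[1L, 2L] - 1L, nb - p[res$count, 2L])
  sk <- if (res$count > 1L)
    max(diff(p[, 1L]) - 1L, diff(p[, 2L]) - 1L) else 0L
  # map back to original ordinals
  pairs <- cbind(f$a_keep[p[, 1L]], f$b_keep[p[, 2L]])
  accepted <- res$count >= params$min_aligned_marker_count
  # containment: the read with the smaller overhang on both ends is
  # covered by the other
  structure(list(accepted = accepted, pairs = pairs,
                 aligned_count = res$count, total_skip = res$skip,
                 max_skip_seen = sk, trim_a = trim_a, trim_b = trim_b,
                 contained_a = all(trim_a <= trim_b),
                 contained_b = all(trim_b <= trim_a)),
            class = "marker_alignment")
}

#' @export
print.marker_alignment <- function(x, ...) {
  if (!x$accepted && x$aligned_count == 0L) {
    cat("marker_alignment: rejected (no admissible chain)\n")
  } else {
    cat("marker_alignment:", x$aligned_count, "aligned markers",
        if (!x$accepted) "(rejected: below minimum)", "\n")
  }
  invisible(x)
}
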