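#' Build the k-nearest-neighbour read graph
#'
#' Vertices are oriented reads (two per read); an edge is an accepted
#' marker alignment between two oriented reads. To tame the high
#' connectivity of repeat regions, each vertex marks only its
#' `max_alignment_count` best incident alignments (most aligned markers;
#' ties by smaller total skip, then smaller partner read id) and an edge
#' survives if either endpoint marks it — so a vertex's degree can still
#' exceed the cutoff. Edges are represented canonically (read pair plus
#' relative strand), which makes the graph strand-symmetric by
#' construction. Cross-strand self-alignments (a read against its own
#' reverse complement) are excluded upstream and would be logged, not
#' removed, if present.
#'
#' @param alignments data.frame with one row per accepted canonical
#'   alignment: columns `r1`, `r2`, `same_strand`, `aligned_count`,
#'   `total_skip`.
#' @param max_alignment_count Alignments marked per vertex (default 6).
#' @return Object of class `read_graph`: the input table with a logical
#'   `kept` column, plus the cutoff used.
#' @export
build_read_graph <- function(alignments, max_alignment_count = 6L) {
  al <- as.data.frame(alignments)
  n <- nrow(al)
  kept <- logical(n)
  if (n > 0L) {
    # by strand symmetry it suffices to rank once per read: the incident
    # alignments of (r, +) and (r, -) are mirror images with equal counts
    for (r in unique(c(al$r1, al$r2))) {
      inc <- which(al$r1 == r | al$r2 == r)
      partner <- ifelse(al$r1[inc] == r, al$r2[inc], al$r1[inc])
      o <- order(-al$aligned_count[inc], al$total_skip[inc], partner)
      kept[inc[head(o, max_alignment_count)]] <- TRUE
    }
  }
  al$kept <- kept
  structure(list(alignments = al,
                 max_alignment_count = as.integer(max_alignment_count)),
            class = "read_graph")
}

#' @export
print.read_graph <- function(x, ...) {
  cat("read_graph:", nrow(x$alignments), "canonical alignments,",
      sum(x$alignments$kept), "kept (k =", x$max_alignment_count, ")\n")
  invisible(x)
}
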