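#' Parameters for marker-graph simplification
#'
#' @param min_coverage,max_coverage Vertex coverage bounds; merged marker
#'   groups outside \[min, max\] are removed (defaults 10, 100).
#' @param max_distance Reachability horizon, in marker-graph edges, of the
#'   approximate transitive reduction (default 30).
#' @param low_coverage_threshold Edges with coverage at or below this are
#'   removed unconditionally (default 0, i.e. none).
#' @param high_coverage_threshold Edges with (saturated) coverage at or
#'   above this are never candidates for transitive reduction
#'   (default 256, i.e. all are candidates since coverage saturates at 255).
#' @param edge_marker_skip_threshold Coverage-1 edges whose single
#'   supporting read skips more markers than this are removed (default 100).
#' @param prune_iterations Leaf-pruning iterations; removes side branches
#'   up to this many edges long (default 6).
#' @param simplify_max_length Nondecreasing length thresholds (in marker
#'   graph edges) for the bubble/superbubble removal iterations
#'   (default 10, 100, 1000).
#' @return A `simplify_params` list.
#' @export
simplify_params <- function(min_coverage = 10L, max_coverage = 100L,
                            max_distance = 30L, low_coverage_threshold = 0L,
                            high_coverage_threshold = 256L,
                            edge_marker_skip_threshold = 100L,
                            prune_iterations = 6L,
                            simplify_max_length = c(10L, 100L, 1000L)) {
  stopifnot(min_coverage >= 1, max_coverage >= min_coverage,
            max_distance >= 1, prune_iterations >= 0,
            !is.unsorted(simplify_max_length))
  structure(list(min_coverage = as.integer(min_coverage),
                 max_coverage = as.integer(max_coverage),
                 max_distance = as.integer(max_distance),
                 low_coverage_threshold = as.integer(low_coverage_threshold),
                 high_coverage_threshold = as.integer(high_coverage_threshold),
                 edge_marker_skip_threshold = as.integer(edge_marker_skip_threshold),
                 prune_iterations = as.integer(prune_iterations),
                 simplify_max_length = as.integer(simplify_max_length)),
            class = "simplify_params")
}

#' Build the global marker graph
#'
#' Every marker occurrence of every oriented read starts as its own
#' vertex; for each accepted alignment of the read graph, vertices of
#' aligned markers are merged (disjoint-set union), together with the
#' mirrored merges on the opposite strands so the graph stays
#' strand-symmetric. Merged groups with coverage (member count) outside
#' \[min_coverage, max_coverage\] are removed. An edge v0 -> v1 is created
#' whenever some read contributes to both vertices and all its markers in
#' between belong to removed vertices; the intervening read sequence is
#' recoverable from the stored positions.
#'
#' @param reads_rle List of `rle_seq`, one per read (forward orientation).
#' @param markers_fwd,markers_rev Lists of `marker_seq` per read.
#' @param alignments List of accepted alignments, each a list with `r1`,
#'   `r2`, `same_strand` and the `pairs` ordinal matrix from
#'   [align_markers()] (computed between r1 forward and r2 in
#'   `same_strand` orientation).
#' @param min_coverage,max_coverage Vertex coverage bounds.
#' @param k Marker length.
#' @return An object of class `marker_graph`.
#' @export
build_marker_graph <- function(reads_rle, markers_fwd, markers_rev,
                               alignments, min_coverage = 10L,
                               max_coverage = 100L, k) {
  nr <- length(reads_rle)
  oriented_mk <- c(markers_fwd, markers_rev)   # o = r fwd, nr + r rev
  rle_or <- c(reads_rle, lapply(reads_rle, rle_revcomp))
  n_o <- vapply(oriented_mk, function(m) length(m$ids), integer(1))
  off <- c(0L, cumsum(n_o))
  ncell <- off[length(off)]

  merge_list <- lapply(alignments, function(al) {
    o1 <- al$r1
    o2 <- if (al$same_strand) al$r2 else nr + al$r2
    p <- al$pairs
    c1 <- off[o1] + p[, 1L]
    c2 <- off[o2] + p[, 2L]
    # mirrored merges on the opposite strands
    o1m <- nr + al$r1
    o2m <- if (al$same_strand) nr + al$r2 else al$r2
    c1m <- off[o1m] + (n_o[o1] + 1L - p[, 1L])
    c2m <- off[o2m] + (n_o[o2] + 1L - p[, 2L])
    cbind(c(c1, c1m), c(c2, c2m))
  })
  merges <- if (length(merge_list)) do.call(rbind, merge_list)
            else matrix(integer(0), 0, 2)
  rep_of <- .union_find(ncell, merges)

  cov_of_rep <- tabulate(rep_of, nbins = ncell)
  keep_rep <- which(cov_of_rep >= min_coverage & cov_of_rep <= max_coverage)
  v_of_rep <- rep(NA_integer_, ncell)
  v_of_rep[keep_rep] <- seq_along(keep_rep)
  v_of_cell <- v_of_rep[rep_of]
  nv <- length(keep_rep)

  # members of surviving vertices
  o_of_cell <- rep.int(seq_len(2L * nr), n_o)
  ord_of_cell <- sequence(n_o)
  pos_of_cell <- unlist(lapply(oriented_mk, `[[`, "pos"), use.names = FALSE)
  keep_cells <- which(!is.na(v_of_cell))
  members <- data.table::data.table(v = v_of_cell[keep_cells],
                                    o = o_of_cell[keep_cells],
                                    ord = ord_of_cell[keep_cells],
                                    pos = pos_of_cell[keep_cells])
  data.table::setorderv(members, c("v", "o", "ord"))

  # reverse-complement vertex pairing, from each vertex's first member
  first_member <- members[!duplicated(members$v), ]
  rc_v <- rep(NA_integer_, nv)
  om <- ifelse(first_member$o <= nr, first_member$o + nr, first_member$o - nr)
  rc_cell <- off[om] + (n_o[first_member$o] + 1L - first_member$ord)
  rc_v[first_member$v] <- v_of_cell[rc_cell]

  # vertex k-mer sequence
  kmer <- substr(vapply(first_member$o, function(o) rle_or[[o]]$bases, ""),
                 first_member$pos, first_member$pos + k - 1L)
  # first_member is ordered by v = 1..nv
  vertices <- data.table::data.table(v = first_member$v,
                                     coverage = cov_of_rep[keep_rep],
                                     kmer = kmer,
                                     rc_v = rc_v[first_member$v])

  # edge occurrences: consecutive surviving markers within each oriented read
  occ_list <- lapply(seq_len(2L * nr), function(o) {
    idx <- seq.int(off[o] + 1L, length.out = n_o[o])
    vs <- v_of_cell[idx]
    ok <- which(!is.na(vs))
    if (length(ok) < 2L) return(NULL)
    a <- ok[-length(ok)]; b <- ok[-1L]
    list(o = rep.int(o, length(a)), ord0 = a, ord1 = b,
         pos0 = oriented_mk[[o]]$pos[a], pos1 = oriented_mk[[o]]$pos[b],
         v0 = vs[a], v1 = vs[b])
  })
  occ_list <- occ_list[!vapply(occ_list, is.null, TRUE)]
  occ <- if (length(occ_list))
    data.table::rbindlist(lapply(occ_list, data.table::as.data.table))
  else data.table::data.table(o = integer(0), ord0 = integer(0),
                              ord1 = integer(0), pos0 = integer(0),
                              pos1 = integer(0), v0 = integer(0),
                              v1 = integer(0))
  data.table::setorderv(occ, c("v0", "v1", "o", "ord0"))
  grp <- cumsum(!duplicated(occ[, c("v0", "v1")]))
  occ$e <- grp
  edges <- occ[, list(v0 = v0[1L], v1 = v1[1L], coverage = .N,
                      skip1 = max(ord1 - ord0) - 1L), by = "e"]
  edges$removed <- FALSE

  # reverse-complement edge pairing
  key <- paste(edges$v0, edges$v1)
  rc_key <- paste(rc_v[edges$v1], rc_v[edges$v0])
  rc_edge <- edges$e[match(rc_key, key)]

  # row indices by vertex / edge for O(1) access during consensus
  members_idx <- split(seq_len(nrow(members)),
                       factor(members$v, levels = seq_len(nv)))
  occ_idx <- split(seq_len(nrow(occ)),
                   factor(occ$e, levels = seq_len(nrow(edges))))
  structure(list(k = as.integer(k), n_reads = nr, vertices = vertices,
                 members = members, edges = edges, occ = occ,
                 members_idx = members_idx, occ_idx = occ_idx,
                 rc_v = rc_v, rc_edge = rc_edge, rle_or = rle_or),
            class = "marker_graph")
}

#' @export
print.marker_graph <- function(x, ...) {
  cat("marker_graph:", nrow(x$vertices), "vertices,", nrow(x$edges),
      "edges (", sum(!x$edges$removed), "alive )\n")
  invisible(x)
}

#' @noRd
mg_remove_edges <- function(mg, eids) {
  eids <- unique(c(eids, mg$rc_edge[eids]))
  eids <- eids[!is.na(eids)]
  if (length(eids))
    data.table::set(mg$edges, i = eids, j = "removed", value = TRUE)
  invisible(mg)
}

#' @noRd
mg_out_adj <- function(mg) {
  split(mg$edges$e, factor(mg$edges$v0, levels = seq_len(nrow(mg$vertices))))
}

#' Approximate transitive reduction of the marker graph
#'
#' Removes, in order: (1) edges with coverage at or below the low
#' threshold; (2) coverage-1 edges whose single supporting read has a
#' marker skip above `edge_marker_skip_threshold`; (3) processing the
#' remaining edges below the high coverage threshold in order of
#' increasing coverage, any edge v0 -> v1 for which an alternative path of
#' at most `max_distance` surviving edges from v0 to v1 exists. Because a
#' witness path is required before removal, reachability within the
#' horizon is never reduced. Removals are mirrored on the opposite strand.
#'
#' @param mg A `marker_graph`.
#' @param params A [simplify_params()] list.
#' @return The graph, with removal flags updated. Side branches caused by
#'   read errors largely disappear in this step.
#' @export
transitive_reduction <- function(mg, params = simplify_params()) {
  ed <- mg$edges
  mg_remove_edges(mg, ed$e[!ed$removed &
                             ed$coverage <= params$low_coverage_threshold])
  mg_remove_edges(mg, ed$e[!ed$removed & ed$coverage == 1L &
                             ed$skip1 > params$edge_marker_skip_threshold])
  cand <- ed[!ed$removed & pmin(ed$coverage, 255L) <
               params$high_coverage_threshold, ]
  cand <- cand[order(cand$coverage, cand$e), ]
  if (nrow(cand) == 0L) return(invisible(mg))
  adj <- mg_out_adj(mg)
  v1s <- ed$v1
  removed <- ed$removed    # local copy, kept in sync
  for (idx in seq_len(nrow(cand))) {
    e <- cand$e[idx]
    if (removed[e]) next
    v0 <- cand$v0[idx]; v1 <- cand$v1[idx]
    frontier <- v0
    seen <- v0
    found <- FALSE
    for (d in seq_len(params$max_distance)) {
      eids <- unlist(adj[frontier], use.names = FALSE)
      eids <- eids[!removed[eids] & eids != e]
      if (!length(eids)) break
      nxt <- unique(v1s[eids])
      if (any(nxt == v1)) { found <- TRUE; break }
      frontier <- setdiff(nxt, seen)
      if (!length(frontier)) break
      seen <- c(seen, frontier)
    }
    if (found) {
      mg_remove_edges(mg, e)
      removed[e] <- TRUE
      rc <- mg$rc_edge[e]
      if (!is.na(rc)) removed[rc] <- TRUE
    }
  }
  invisible(mg)
}

#' Prune short side branches (leaves)
#'
#' Each iteration removes every edge whose source has in-degree 0 or whose
#' target has out-degree 0 (over surviving edges), so after n iterations
#' all dead-end branches of up to n edges are gone; isolated leaf vertices
#' are tolerated. Cycles are untouched.
#'
#' @param mg A `marker_graph`.
#' @param iterations Number of pruning iterations (default 6).
#' @return The graph, with removal flags updated.
#' @export
prune_leaves <- function(mg, iterations = 6L) {
  nv <- nrow(mg$vertices)
  for (i in seq_len(iterations)) {
    ed <- mg$edges[!mg$edges$removed, ]
    if (nrow(ed) == 0L) break
    in_deg <- tabulate(ed$v1, nbins = nv)
    out_deg <- tabulate(ed$v0, nbins = nv)
    rem <- ed$e[in_deg[ed$v0] == 0L | out_deg[ed$v1] == 0L]
    if (!length(rem)) break
    mg_remove_edges(mg, rem)
  }
  invisible(mg)
}
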