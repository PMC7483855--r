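#' Condense the marker graph into an assembly graph
#'
#' Each maximal linear chain of surviving marker-graph edges (through
#' vertices of in-degree one and out-degree one) becomes a single assembly
#' edge. An edge's length is the number of constituent marker-graph edges
#' and its average coverage is the mean of their coverages. Assembly edges
#' come in reverse-complement pairs (occasionally self-paired), of which
#' only one per pair is assembled to sequence.
#'
#' @param mg A `marker_graph`.
#' @return Object of class `assembly_graph`: `edges` data.table (`a`,
#'   `source`, `target`, `length`, `avg_cov`, `rc_a`), `chains` list of
#'   marker-edge id vectors, and `aedge_of` mapping marker edges to their
#'   assembly edge.
#' @export
build_assembly_graph <- function(mg) {
  ed <- mg$edges[!mg$edges$removed, ]
  nv <- nrow(mg$vertices)
  ne_all <- nrow(mg$edges)
  if (nrow(ed) == 0L) {
    return(structure(list(edges = data.table::data.table(
      a = integer(0), source = integer(0), target = integer(0),
      length = integer(0), avg_cov = numeric(0), rc_a = integer(0)),
      chains = list(), aedge_of = rep(NA_integer_, ne_all)),
      class = "assembly_graph"))
  }
  in_deg <- tabulate(ed$v1, nbins = nv)
  out_deg <- tabulate(ed$v0, nbins = nv)
  interior <- in_deg == 1L & out_deg == 1L
  # single alive out-edge per vertex with out-degree 1
  out1 <- rep(NA_integer_, nv)
  o1 <- ed[out_deg[ed$v0] == 1L, ]
  out1[o1$v0] <- o1$e
  v0_of <- rep(NA_integer_, ne_all); v0_of[ed$e] <- ed$v0
  v1_of <- rep(NA_integer_, ne_all); v1_of[ed$e] <- ed$v1
  cov_of <- rep(NA_real_, ne_all); cov_of[ed$e] <- ed$coverage

  covered <- rep(FALSE, ne_all)
  chains <- list()
  walk <- function(e0) {
    chain <- e0
    covered[e0] <<- TRUE
    v <- v1_of[e0]
    while (interior[v]) {
      e2 <- out1[v]
      if (is.na(e2) || covered[e2]) break
      chain <- c(chain, e2)
      covered[e2] <<- TRUE
      v <- v1_of[e2]
    }
    chain
  }
  starts <- ed$e[!interior[ed$v0]]
  for (e0 in starts) chains[[length(chains) + 1L]] <- walk(e0)
  # leftovers are isolated cycles: start each at its smallest edge id
  repeat {
    left <- ed$e[!covered[ed$e]]
    if (!length(left)) break
    chains[[length(chains) + 1L]] <- walk(min(left))
  }
  na <- length(chains)
  aedge_of <- rep(NA_integer_, ne_all)
  for (i in seq_len(na)) aedge_of[chains[[i]]] <- i
  firsts <- vapply(chains, `[`, integer(1), 1L)
  lasts <- vapply(chains, function(ch) ch[length(ch)], integer(1))
  rc_last <- mg$rc_edge[lasts]
  rc_a <- ifelse(is.na(rc_last), NA_integer_, aedge_of[rc_last])
  edges <- data.table::data.table(
    a = seq_len(na),
    source = v0_of[firsts],
    target = v1_of[lasts],
    length = lengths(chains),
    avg_cov = vapply(chains, function(ch) mean(cov_of[ch]), numeric(1)),
    rc_a = rc_a)
  structure(list(edges = edges, chains = chains, aedge_of = aedge_of),
            class = "assembly_graph")
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat("assembly_graph:", nrow(x$edges), "edges; lengths",
      paste(sort(x$edges$length, decreasing = TRUE), collapse = " "), "\n")
  invisible(x)
}

#' Remove bubbles (parallel assembly edges)
#'
#' Bubbles appear in the assembly graph as sets of parallel edges with the
#' same source and target. Where every branch is at most `max_length`
#' marker-graph edges long, only the branch with the highest average
#' coverage is kept (ties: longer branch, then the lexicographically
#' smallest chain of vertex ids); the marker-graph edges of the other
#' branches are flagged as removed.
#'
#' @param mg A `marker_graph`.
#' @param max_length Length threshold in marker-graph edges.
#' @return The marker graph, with removal flags updated.
#' @export
remove_bubbles <- function(mg, max_length) {
  ag <- build_assembly_graph(mg)
  ae <- ag$edges
  if (nrow(ae) == 0L) return(invisible(mg))
  key <- paste(ae$source, ae$target)
  tab <- table(key)
  for (kk in names(tab)[tab >= 2L]) {
    rows <- which(key == kk)
    if (any(ae$length[rows] > max_length)) next
    vkey <- vapply(rows, function(r)
      paste(c(ae$source[r], mg$edges$v1[ag$chains[[r]]]), collapse = ","), "")
    o <- order(-ae$avg_cov[rows], -ae$length[rows], vkey)
    losers <- rows[o[-1L]]
    mg_remove_edges(mg, unlist(ag$chains[losers], use.names = FALSE))
  }
  invisible(mg)
}

#' Remove superbubbles (clusters of short assembly edges)
#'
#' Connected components of the assembly graph over edges of length at most
#' `max_length` form clusters. Entries are cluster vertices with an
#' incoming assembly edge from outside the cluster; exits have an outgoing
#' edge to the outside. For every entry/exit pair the shortest path
#' through the cluster is computed with edge length defined as the inverse
#' of average coverage; edges on some shortest path are kept and all other
#' intra-cluster short edges are removed. Clusters without any
#' entry-to-exit path are left untouched.
#'
#' @inheritParams remove_bubbles
#' @return The marker graph, with removal flags updated.
#' @export
remove_superbubbles <- function(mg, max_length) {
  ag <- build_assembly_graph(mg)
  ae <- ag$edges
  short <- ae$length <= max_length
  if (!any(short)) return(invisible(mg))
  g_short <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ae$source[short]),
               to = as.character(ae$target[short]),
               a = ae$a[short]),
    directed = TRUE)
  comp <- igraph::components(g_short, mode = "weak")
  vnames <- igraph::V(g_short)$name
  for (ci in seq_len(comp$no)) {
    vc <- as.integer(vnames[comp$membership == ci])
    in_c_s <- short & ae$source %in% vc & ae$target %in% vc
    ec <- which(in_c_s)
    if (!length(ec)) next
    entries <- unique(ae$target[!(ae$source %in% vc) & ae$target %in% vc])
    exits <- unique(ae$source[ae$source %in% vc & !(ae$target %in% vc)])
    if (!length(entries) || !length(exits)) next
    sub <- igraph::graph_from_data_frame(
      data.frame(from = as.character(ae$source[ec]),
                 to = as.character(ae$target[ec])),
      directed = TRUE,
      vertices = data.frame(name = as.character(vc)))
    w <- 1 / ae$avg_cov[ec]
    keep <- logical(length(ec))
    dmat <- igraph::distances(sub, v = as.character(entries),
                              to = as.character(exits), mode = "out",
                              weights = w)
    any_path <- FALSE
    for (ei in seq_along(entries)) {
      reach <- exits[is.finite(dmat[ei, ])]
      if (!length(reach)) next
      any_path <- TRUE
      # a zero-length path (entry == exit) is valid and keeps nothing
      to <- setdiff(reach, entries[ei])
      if (!length(to)) next
      sp <- igraph::shortest_paths(sub, from = as.character(entries[ei]),
                                   to = as.character(to),
                                   weights = w, mode = "out",
                                   output = "epath")
      for (ep in sp$epath)
        if (length(ep)) keep[as.integer(ep)] <- TRUE
    }
    if (!any_path) next
    drop <- ec[!keep]
    if (length(drop))
      mg_remove_edges(mg, unlist(ag$chains[drop], use.names = FALSE))
  }
  invisible(mg)
}

#' Iterative bubble and superbubble removal
#'
#' Applies one round of [remove_bubbles()] followed by
#' [remove_superbubbles()] per threshold, in ascending order, so small
#' error-induced features are resolved before larger (e.g. heterozygous)
#' ones. With the default thresholds the surviving graph is mostly linear.
#'
#' @param mg A `marker_graph` (after transitive reduction and pruning).
#' @param simplify_max_length Nondecreasing integer thresholds.
#' @return The marker graph, with removal flags updated.
#' @export
simplify_marker_graph <- function(mg, simplify_max_length = c(10L, 100L, 1000L)) {
  for (thr in simplify_max_length) {
    remove_bubbles(mg, thr)
    remove_superbubbles(mg, thr)
  }
  invisible(mg)
}
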