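#' Column-majority consensus of short RLE base strings
#'
#' Progressive profile alignment anchored at both ends (all contributing
#' reads share identical flanking markers by construction), followed by
#' per-column majority. Inputs are sorted internally (longest first, then
#' lexicographic) so the result does not depend on read order; column
#' ties prefer a base over a gap and the alphabetically smallest base.
#'
#' @param sequences Character vector of RLE base strings (may include "").
#' @param match,mismatch,gap Alignment scores (defaults 2, -1, -1.5).
#' @return List: `consensus` string and `map`, an integer matrix (one row
#'   per input sequence, in input order) giving the 1-based source
#'   position behind each consensus column (0 = gap).
#' @export
msa_consensus <- function(sequences, match = 2, mismatch = -1, gap = -1.5) {
  stopifnot(length(sequences) >= 1L)
  o <- order(-nchar(sequences), sequences)
  res <- .msa_consensus(sequences[o], match, mismatch, gap)
  map <- res$map
  map[o, ] <- res$map
  list(consensus = res$consensus, map = map)
}

#' Most frequent repeat count, ties to the smaller value
#'
#' @param observations Nonempty integer vector of observed repeat counts.
#' @return The modal value; on ties, the smallest tied value.
#' @export
plurality_repeat_count <- function(observations) {
  stopifnot(length(observations) >= 1L)
  tab <- tabulate(observations)
  m <- max(tab)
  which(tab == m)[1L]
}

#' @noRd
vertex_piece <- function(mg, v) {
  ridx <- mg$members_idx[[v]]
  mem <- mg$members[ridx, ]
  k <- mg$k
  bases <- strsplit(mg$vertices$kmer[v], "", fixed = TRUE)[[1L]]
  obs <- vector("list", k)
  cnts <- lapply(seq_len(nrow(mem)), function(i)
    mg$rle_or[[mem$o[i]]]$counts[mem$pos[i]:(mem$pos[i] + k - 1L)])
  for (j in seq_len(k))
    obs[[j]] <- vapply(cnts, `[`, integer(1), j)
  list(bases = bases, obs = obs)
}

#' @noRd
edge_piece <- function(mg, e) {
  ridx <- mg$occ_idx[[e]]
  oc <- mg$occ[ridx, ]
  k <- mg$k
  gap <- oc$pos1 - (oc$pos0 + k)
  is_gap <- gap > 0L
  # hybrid: keep the majority kind (ties resolved to the overlap kind)
  if (any(is_gap) && any(!is_gap)) {
    keep <- if (sum(is_gap) > sum(!is_gap)) is_gap else !is_gap
    oc <- oc[keep, ]; gap <- gap[keep]; is_gap <- is_gap[keep]
  }
  if (!any(is_gap)) {
    # overlapping or abutting markers: consensus number of overlapping
    # bases is the most frequent one (ties to the smaller overlap)
    ov <- -gap
    tab <- table(ov)
    m <- max(tab)
    ov_cons <- as.integer(names(tab)[tab == m][1L])
    return(list(kind = "overlap", overlap = ov_cons))
  }
  seqs <- substr(vapply(oc$o, function(o) mg$rle_or[[o]]$bases, ""),
                 oc$pos0 + k, oc$pos1 - 1L)
  cons <- msa_consensus(seqs)
  nc <- nchar(cons$consensus)
  if (nc == 0L) return(list(kind = "overlap", overlap = 0L))
  bases <- strsplit(cons$consensus, "", fixed = TRUE)[[1L]]
  obs <- vector("list", nc)
  schars <- strsplit(seqs, "", fixed = TRUE)
  for (j in seq_len(nc)) {
    q <- cons$map[, j]
    src <- which(q > 0L)
    src <- src[vapply(src, function(t) schars[[t]][q[t]], "") == bases[j]]
    obs[[j]] <- vapply(src, function(t)
      mg$rle_or[[oc$o[t]]]$counts[oc$pos0[t] + k - 1L + q[t]], integer(1))
  }
  list(kind = "gap", bases = bases, obs = obs)
}

#' Assemble run-length consensus along a marker-graph path
#'
#' Traverses the path vertex to edge to vertex. Vertices contribute their
#' marker sequence verbatim (all contributing reads agree by
#' construction), with per-read repeat-count observations collected at
#' every position. Edges contribute according to whether the adjacent
#' markers overlap (consensus overlap length), leave a gap (constrained
#' multiple-alignment consensus of the intervening read sequences), or
#' are a hybrid of both kinds (minority kind discarded first).
#'
#' @param chain Integer vector of surviving marker-graph edge ids forming
#'   a path (e.g. one element of `build_assembly_graph(mg)$chains`).
#' @param mg The `marker_graph`.
#' @return Object of class `path_consensus`: `bases` (character vector,
#'   one RLE base per position), `obs` (list of integer repeat-count
#'   observation vectors, nonempty at every position) and `coverage`
#'   (observations per position).
#' @export
assemble_path_sequence <- function(chain, mg) {
  stopifnot(length(chain) >= 1L)
  if (!all(mg$edges$v0[chain[-1L]] == mg$edges$v1[chain[-length(chain)]]))
    stop_invalid("chain is not a path in the marker graph")
  pieces <- vector("list", 2L * length(chain) + 1L)
  np <- 0L
  add <- function(p, overlap = 0L) {
    np <<- np + 1L
    p$overlap <- overlap
    pieces[[np]] <<- p
  }
  add(vertex_piece(mg, mg$edges$v0[chain[1L]]))
  for (e in chain) {
    ep <- edge_piece(mg, e)
    if (ep$kind == "gap") {
      add(ep)
      add(vertex_piece(mg, mg$edges$v1[e]))
    } else {
      add(vertex_piece(mg, mg$edges$v1[e]), overlap = ep$overlap)
    }
  }
  pieces <- pieces[seq_len(np)]
  lens <- vapply(pieces, function(p) length(p$bases), integer(1))
  total <- sum(lens - vapply(pieces, `[[`, integer(1), "overlap"))
  res_b <- character(total)
  res_obs <- vector("list", total)
  cur <- 0L
  for (p in pieces) {
    start <- cur - p$overlap
    for (j in seq_along(p$bases)) {
      pp <- start + j
      if (pp <= cur) {
        res_obs[[pp]] <- c(res_obs[[pp]], p$obs[[j]])
      } else {
        res_b[pp] <- p$bases[j]
        res_obs[[pp]] <- p$obs[[j]]
      }
    }
    cur <- start + length(p$bases)
  }
  structure(list(bases = res_b, obs = res_obs,
                 coverage = lengths(res_obs)),
            class = "path_consensus")
}

#' Expand a run-length consensus to raw sequence
#'
#' Each position's repeat count is decoded as the plurality of the
#' per-read observations (ties to the smaller count).
#'
#' @param pc A `path_consensus`.
#' @return The raw contig as a single string.
#' @export
decode_assembly <- function(pc) {
  counts <- vapply(pc$obs, plurality_repeat_count, integer(1))
  paste0(strrep(pc$bases, counts), collapse = "")
}

#' @export
print.path_consensus <- function(x, ...) {
  cat("path_consensus:", length(x$bases), "RLE positions, mean coverage",
      round(mean(x$coverage), 1), "\n")
  invisible(x)
}
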