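#' Assemble long reads into contigs
#'
#' Runs the full pipeline: run-length encoding (rejecting unusable
#' reads), marker selection and lookup, candidate-pair detection by
#' threshold MinHash, banded marker-space alignment, k-nearest-neighbour
#' read graph, marker-graph construction and simplification (approximate
#' transitive reduction, leaf pruning, bubble and superbubble removal),
#' condensation to the assembly graph, and run-length consensus with
#' plurality repeat-count decoding. Deterministic given the seed in
#' `params`.
#'
#' @param reads Named character vector of read sequences (see
#'   [read_sequences()]).
#' @param params An [assembly_params()] list.
#' @param verbose Log per-stage counters (default TRUE).
#' @return Object of class `nanoasm_assembly`: `contigs` (named character
#'   vector, raw sequence), `paths` (per-contig `path_consensus`),
#'   `marker_graph`, `assembly_graph`, `marker_set`, `read_rle`,
#'   `contigs_by_aedge`, `stats` and `params`.
#' @export
assemble_reads <- function(reads, params = assembly_params(),
                           verbose = TRUE) {
  log_ <- function(...) if (verbose) message(sprintf(...))
  stats <- list()
  t0 <- proc.time()[["elapsed"]]

  rle_list <- vector("list", length(reads))
  ok <- logical(length(reads))
  for (i in seq_along(reads)) {
    rle_list[[i]] <- tryCatch(rle_encode(reads[[i]]),
                              nanoasm_read_rejected = function(e) NULL)
    ok[i] <- !is.null(rle_list[[i]])
  }
  stats$reads_in <- length(reads)
  stats$reads_rejected <- sum(!ok)
  if (stats$reads_rejected > 0L)
    warning(sprintf("%d read(s) rejected at ingest", stats$reads_rejected))
  rle_list <- rle_list[ok]
  read_names <- names(reads)[ok] %||% paste0("read_", which(ok))
  nr <- length(rle_list)
  log_("reads kept: %d / %d", nr, stats$reads_in)

  ms <- select_markers(params$kmers_k, params$kmers_probability,
                       derive_seed(params$seed, 1L))
  stats$marker_count <- length(ms$members)
  mk_fwd <- lapply(rle_list, find_markers, ms = ms)
  mk_rev <- lapply(mk_fwd, marker_seq_revcomp, ms = ms)
  log_("markers: %d distinct; mean per read %.0f", stats$marker_count,
       mean(vapply(mk_fwd, length, integer(1))))

  lhp <- lowhash_params(m = params$minhash_m,
                        hash_fraction = params$minhash_hash_fraction,
                        iterations = params$minhash_iterations,
                        max_bucket_size = params$minhash_max_bucket_size,
                        min_frequency = params$minhash_min_frequency,
                        seed = derive_seed(params$seed, 2L))
  cand <- find_candidate_pairs(lapply(mk_fwd, `[[`, "ids"),
                               lapply(mk_rev, `[[`, "ids"), lhp)
  stats$candidate_pairs <- nrow(cand)
  log_("candidate pairs: %d", nrow(cand))

  ap <- align_params(params$align_max_skip, params$align_max_trim,
                     params$align_max_marker_frequency,
                     params$align_min_aligned_marker_count)
  alns <- vector("list", nrow(cand))
  summ <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- mk_fwd[[cand$r1[i]]]
    b <- if (cand$same_strand[i]) mk_fwd[[cand$r2[i]]] else mk_rev[[cand$r2[i]]]
    al <- align_markers(a, b, ap)
    if (!al$accepted) next
    alns[[i]] <- list(r1 = cand$r1[i], r2 = cand$r2[i],
                      same_strand = cand$same_strand[i], pairs = al$pairs)
    summ[[i]] <- data.frame(r1 = cand$r1[i], r2 = cand$r2[i],
                            same_strand = cand$same_strand[i],
                            aligned_count = al$aligned_count,
                            total_skip = al$total_skip)
  }
  keep <- !vapply(alns, is.null, TRUE)
  alns <- alns[keep]
  summ <- do.call(rbind, summ[keep])
  stats$alignments_kept <- length(alns)
  log_("accepted alignments: %d", length(alns))

  rg <- if (length(alns))
    build_read_graph(summ, params$read_graph_max_alignment_count)
  else NULL
  alns_rg <- if (!is.null(rg)) alns[rg$alignments$kept] else list()
  stats$read_graph_edges <- length(alns_rg)
  log_("read graph edges (canonical): %d", length(alns_rg))

  mg <- build_marker_graph(rle_list, mk_fwd, mk_rev, alns_rg,
                           min_coverage = params$mg_min_coverage,
                           max_coverage = params$mg_max_coverage,
                           k = params$kmers_k)
  stats$mg_vertices <- nrow(mg$vertices)
  stats$mg_edges <- nrow(mg$edges)
  log_("marker graph: %d vertices, %d edges", nrow(mg$vertices),
       nrow(mg$edges))

  sp <- simplify_params(min_coverage = params$mg_min_coverage,
                        max_coverage = params$mg_max_coverage,
                        max_distance = params$mg_max_distance,
                        low_coverage_threshold = params$mg_low_coverage_threshold,
                        high_coverage_threshold = params$mg_high_coverage_threshold,
                        edge_marker_skip_threshold =
                          params$mg_edge_marker_skip_threshold,
                        prune_iterations = params$mg_prune_iterations,
                        simplify_max_length = params$mg_simplify_max_length)
  transitive_reduction(mg, sp)
  stats$edges_after_reduction <- sum(!mg$edges$removed)
  prune_leaves(mg, sp$prune_iterations)
  stats$edges_after_pruning <- sum(!mg$edges$removed)
  simplify_marker_graph(mg, sp$simplify_max_length)
  stats$edges_after_simplify <- sum(!mg$edges$removed)
  log_("edges alive after reduction/prune/simplify: %d / %d / %d",
       stats$edges_after_reduction, stats$edges_after_pruning,
       stats$edges_after_simplify)

  ag <- build_assembly_graph(mg)
  ae <- ag$edges
  sel <- ae$a[is.na(ae$rc_a) | ae$a <= ae$rc_a]
  sel <- sel[order(-ae$length[sel])]
  contigs <- character(0)
  paths <- list()
  by_aedge <- character(0)
  for (a in sel) {
    pc <- assemble_path_sequence(ag$chains[[a]], mg)
    raw <- decode_assembly(pc)
    nm <- paste0("contig_", length(contigs) + 1L)
    contigs[nm] <- raw
    paths[[nm]] <- pc
    by_aedge[as.character(a)] <- raw
  }
  stats$n_contigs <- length(contigs)
  stats$assembly_edges <- nrow(ae)
  stats$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 1)
  log_("assembly graph: %d edges; %d contigs; N50 %d; %.1fs",
       nrow(ae), length(contigs),
       if (length(contigs)) n50(nchar(contigs)) else 0L, stats$elapsed_s)

  structure(list(contigs = contigs, paths = paths, marker_graph = mg,
                 assembly_graph = ag, marker_set = ms,
                 read_rle = setNames(rle_list, read_names),
                 contigs_by_aedge = by_aedge, stats = stats,
                 params = params),
            class = "nanoasm_assembly")
}

#' @export
print.nanoasm_assembly <- function(x, ...) {
  cat("nanoasm_assembly:", length(x$contigs), "contig(s), total",
      sum(nchar(x$contigs)), "bp, N50", n50(nchar(x$contigs)), "\n")
  invisible(x)
}

#' Locate a contig in a reference and compute alignment identity
#'
#' Anchors the contig by exact 24-mer seeds, then computes a banded
#' fitting alignment (all of the contig against a substring of the
#' reference window). Identity is `1 - distance / contig length`.
#'
#' @param contig,reference DNA strings.
#' @param band Band half-width for the edit distance (default 1500).
#' @return Named list: `identity`, `edit_distance`, `ref_start`,
#'   `ref_end`. NULL if the contig cannot be anchored.
#' @export
truth_identity <- function(contig, reference, band = 1500L) {
  n <- nchar(contig)
  anchor <- NULL
  for (off in seq(1L, max(1L, n - 24L), by = max(50L, n %/% 40L))) {
    seed <- substr(contig, off, off + 23L)
    hit <- regexpr(seed, reference, fixed = TRUE)
    if (hit > 0L) { anchor <- c(off, as.integer(hit)); break }
  }
  if (is.null(anchor)) {
    rc <- revcomp(contig)
    for (off in seq(1L, max(1L, n - 24L), by = max(50L, n %/% 40L))) {
      seed <- substr(rc, off, off + 23L)
      hit <- regexpr(seed, reference, fixed = TRUE)
      if (hit > 0L) { contig <- rc; anchor <- c(off, as.integer(hit)); break }
    }
    if (is.null(anchor)) return(NULL)
  }
  rs <- max(1L, anchor[2] - anchor[1] + 1L - band %/% 2L)
  re <- min(nchar(reference), anchor[2] + (n - anchor[1]) + band %/% 2L)
  win <- substr(reference, rs, re)
  d <- .banded_fit_distance(contig, win, band)
  if (d < 0) return(NULL)
  list(identity = 1 - d / n, edit_distance = d, ref_start = rs,
       ref_end = re)
}
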