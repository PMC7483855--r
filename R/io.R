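#' Full assembly parameter set
#'
#' Every pipeline parameter is exposed here and on the command line;
#' none are hardcoded. Defaults follow the conventions of the
#' marker-graph assembly approach: k = 10 markers at 10% density,
#' threshold MinHash with 10 iterations, coverage window \[10, 100\] on
#' marker-graph vertices, and bubble removal thresholds 10/100/1000.
#'
#' @param kmers_k,kmers_probability Marker selection.
#' @param minhash_m,minhash_hash_fraction,minhash_iterations,minhash_max_bucket_size,minhash_min_frequency
#'   Candidate-pair detection.
#' @param align_max_skip,align_max_trim,align_max_marker_frequency,align_min_aligned_marker_count
#'   Marker-space alignment.
#' @param read_graph_max_alignment_count k-nearest-neighbour cutoff.
#' @param mg_min_coverage,mg_max_coverage,mg_max_distance,mg_low_coverage_threshold,mg_high_coverage_threshold,mg_edge_marker_skip_threshold,mg_prune_iterations,mg_simplify_max_length
#'   Marker-graph construction and simplification.
#' @param seed Master seed; all stage seeds derive from it.
#' @return An `assembly_params` list.
#' @export
assembly_params <- function(kmers_k = 10L, kmers_probability = 0.1,
                            minhash_m = 4L, minhash_hash_fraction = 0.01,
                            minhash_iterations = 10L,
                            minhash_max_bucket_size = 10L,
                            minhash_min_frequency = 2L,
                            align_max_skip = 30L, align_max_trim = 30L,
                            align_max_marker_frequency = 10L,
                            align_min_aligned_marker_count = 40L,
                            read_graph_max_alignment_count = 6L,
                            mg_min_coverage = 10L, mg_max_coverage = 100L,
                            mg_max_distance = 30L,
                            mg_low_coverage_threshold = 0L,
                            mg_high_coverage_threshold = 256L,
                            mg_edge_marker_skip_threshold = 100L,
                            mg_prune_iterations = 6L,
                            mg_simplify_max_length = c(10L, 100L, 1000L),
                            seed = 1L) {
  p <- list(kmers_k = as.integer(kmers_k),
            kmers_probability = as.numeric(kmers_probability),
            minhash_m = as.integer(minhash_m),
            minhash_hash_fraction = as.numeric(minhash_hash_fraction),
            minhash_iterations = as.integer(minhash_iterations),
            minhash_max_bucket_size = as.integer(minhash_max_bucket_size),
            minhash_min_frequency = as.integer(minhash_min_frequency),
            align_max_skip = as.integer(align_max_skip),
            align_max_trim = as.integer(align_max_trim),
            align_max_marker_frequency = as.integer(align_max_marker_frequency),
            align_min_aligned_marker_count =
              as.integer(align_min_aligned_marker_count),
            read_graph_max_alignment_count =
              as.integer(read_graph_max_alignment_count),
            mg_min_coverage = as.integer(mg_min_coverage),
            mg_max_coverage = as.integer(mg_max_coverage),
            mg_max_distance = as.integer(mg_max_distance),
            mg_low_coverage_threshold = as.integer(mg_low_coverage_threshold),
            mg_high_coverage_threshold = as.integer(mg_high_coverage_threshold),
            mg_edge_marker_skip_threshold =
              as.integer(mg_edge_marker_skip_threshold),
            mg_prune_iterations = as.integer(mg_prune_iterations),
            mg_simplify_max_length = as.integer(mg_simplify_max_length),
            seed = as.integer(seed))
  stopifnot(p$kmers_k >= 1, p$kmers_probability > 0, p$kmers_probability <= 1,
            p$minhash_hash_fraction > 0, p$minhash_hash_fraction <= 1,
            !is.unsorted(p$mg_simplify_max_length))
  structure(p, class = "assembly_params")
}

#' Write / read assembly parameters as JSON
#'
#' The echo file written next to assembly outputs reloads to an identical
#' configuration; unknown keys are rejected.
#'
#' @param params An `assembly_params` list.
#' @param path File path.
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(assembly_params))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop_invalid(paste("unknown parameter keys:", paste(bad, collapse = ", ")))
  do.call(assembly_params, x)
}

#' Read sequences from FASTA or FASTQ (plain or gzip)
#'
#' FASTQ quality strings are ignored (a note is logged). Sequences are
#' uppercased; validation and rejection of unusable reads (ambiguity
#' codes, homopolymer runs over 255) happens at run-length encoding.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (format == "fastq")
    message("note: FASTQ qualities are ignored")
  x <- Biostrings::readDNAStringSet(path, format = format)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*", "", names(x))
  if (anyDuplicated(names(out)))
    stop_invalid("duplicate read ids in input")
  out
}

#' Contig N50
#'
#' The length such that contigs of that length or greater sum to at least
#' half the total assembly length.
#'
#' @param lengths Integer vector of contig lengths.
#' @return The N50 length.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) return(0L)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1L]]
}

#' Write contigs as wrapped FASTA
#'
#' @param contigs Named character vector.
#' @param path Output path.
#' @param width Line width (default 80).
#' @export
write_fasta <- function(contigs, path, width = 80L) {
  x <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Export the assembly graph as GFA 1.0
#'
#' S records hold the assembled chains (raw sequence where assembled,
#' `*` otherwise); L records connect chains sharing a junction vertex.
#'
#' @param asm A `nanoasm_assembly` from [assemble_reads()].
#' @param path Output path.
#' @export
write_gfa <- function(asm, path) {
  ae <- asm$assembly_graph$edges
  lines <- "H\tVN:Z:1.0"
  seqs <- setNames(rep("*", nrow(ae)), as.character(ae$a))
  seqs[names(asm$contigs_by_aedge)] <- asm$contigs_by_aedge
  for (i in seq_len(nrow(ae))) {
    s <- seqs[[as.character(ae$a[i])]]
    lines <- c(lines, paste0("S\t", ae$a[i], "\t", s,
                             "\tLN:i:", nchar(s) %/% 1L))
  }
  for (i in seq_len(nrow(ae))) {
    nxt <- ae$a[ae$source == ae$target[i]]
    for (b in nxt)
      lines <- c(lines, paste0("L\t", ae$a[i], "\t+\t", b, "\t+\t0M"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write per-contig metrics as TSV
#'
#' @param asm A `nanoasm_assembly`.
#' @param path Output path.
#' @export
write_metrics <- function(asm, path) {
  lens <- nchar(asm$contigs)
  df <- data.frame(contig = names(asm$contigs), length = lens,
                   avg_coverage = round(vapply(asm$paths, function(p)
                     mean(p$coverage), numeric(1)), 2))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimal SAM reader for polisher input
#'
#' Parses the subset of SAM needed to band the polisher: query name,
#' flag (strand), reference, 1-based position and CIGAR. Returns 0-based
#' half-open query/reference anchor pairs per alignment derived from the
#' CIGAR match segments.
#'
#' @param path SAM text file.
#' @return data.frame: qname, rname, strand, and per-alignment anchor
#'   list-columns `qpos`/`rpos` (1-based matched coordinates).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t")
  recs <- lapply(f, function(x) {
    flag <- as.integer(x[2])
    if (bitwAnd(flag, 4L) > 0L) return(NULL)   # unmapped
    cig <- x[6]
    ops <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1L]]
    n <- as.integer(sub("[A-Z=]", "", ops))
    op <- sub("[0-9]+", "", ops)
    q <- 1L; r <- as.integer(x[4])
    qa <- integer(0); ra <- integer(0)
    for (t in seq_along(op)) {
      if (op[t] %in% c("M", "=", "X")) {
        qa <- c(qa, q, q + n[t] - 1L); ra <- c(ra, r, r + n[t] - 1L)
        q <- q + n[t]; r <- r + n[t]
      } else if (op[t] %in% c("I", "S")) q <- q + n[t]
      else if (op[t] %in% c("D", "N")) r <- r + n[t]
    }
    list(qname = x[1], rname = x[3],
         strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
         qpos = qa, rpos = ra)
  })
  recs <- recs[!vapply(recs, is.null, TRUE)]
  data.frame(qname = vapply(recs, `[[`, "", "qname"),
             rname = vapply(recs, `[[`, "", "rname"),
             strand = vapply(recs, `[[`, "", "strand"),
             qpos = I(lapply(recs, `[[`, "qpos")),
             rpos = I(lapply(recs, `[[`, "rpos")))
}
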