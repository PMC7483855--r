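#' Generative run-length error model for simulated reads
#'
#' Nanopore basecallers mis-measure homopolymer lengths with a dispersion
#' that grows with the true length. The simulator draws each observed run
#' length x from a discretised double-geometric distribution centred on
#' the true length y, truncated to \[max(1, y-4), min(max_len, y+4)\],
#' with scale 0.35 + 0.06 y. The same object structure is used for models
#' trained from data ([train_runlength_model()]), so the generative model
#' is recoverable by training on simulated reads.
#'
#' @param max_len Largest modelled run length (default 50).
#' @param scale_intercept,scale_slope Scale of the error distribution as a
#'   function of true length (defaults 0.35 and 0.06).
#' @return A `runlength_model`.
#' @export
runlength_error_model <- function(max_len = 50L, scale_intercept = 0.35,
                                  scale_slope = 0.06) {
  mat <- matrix(0, nrow = max_len, ncol = max_len)
  for (y in seq_len(max_len)) {
    xs <- max(1L, y - 4L):min(max_len, y + 4L)
    w <- exp(-abs(xs - y) / (scale_intercept + scale_slope * y))
    mat[y, xs] <- w / sum(w)
  }
  new_runlength_model(list(A = mat, C = mat, G = mat, T = mat), max_len)
}

#' Simulate a genome sequence
#'
#' I.i.d. uniform background with an optional planted interspersed repeat
#' (a segment copied to a second location), deterministic per seed.
#'
#' @param length Genome length in bases (>= 1000).
#' @param seed Integer seed.
#' @param repeat_length Length of a planted duplicated segment (0 = none).
#' @return A DNA string; if a repeat was planted, the attribute
#'   `repeat_at` holds the two copy start positions.
#' @export
simulate_genome <- function(length, seed = 1L, repeat_length = 0L) {
  stopifnot(length >= 1000)
  with_seed(seed, {
    g <- int_to_dna(sample.int(4L, length, replace = TRUE) - 1L)
    if (repeat_length > 0L) {
      stopifnot(repeat_length * 3 < length)
      p1 <- sample.int(length %/% 3 - repeat_length, 1L)
      p2 <- sample.int(length %/% 3 - repeat_length, 1L) + 2L * (length %/% 3)
      seg <- substr(g, p1, p1 + repeat_length - 1L)
      g <- paste0(substr(g, 1L, p2 - 1L), seg,
                  substr(g, p2 + repeat_length, length))
      attr(g, "repeat_at") <- c(p1, p2)
    }
    g
  })
}

#' Simulate nanopore-like reads with a truth layout
#'
#' Reads are sampled uniformly from the genome with random strand, with
#' log-normal lengths (truncated below at `min_length`). Errors are
#' applied in three stages, mirroring the dominant nanopore error modes:
#' (1) every homopolymer's observed length is resampled from the
#' generative run-length confusion model, (2) substitutions at
#' `substitution_rate`, (3) single-base non-homopolymer insertions and
#' deletions at `indel_rate` (half each). With defaults, median read
#' identity is about 90%. Every edit is recorded in a per-read trace from
#' which the read can be replayed exactly ([replay_read()]).
#'
#' @param genome Genome string from [simulate_genome()].
#' @param coverage Target mean coverage.
#' @param seed Integer seed.
#' @param model Generative `runlength_model`
#'   (default [runlength_error_model()]).
#' @param substitution_rate,indel_rate Per-base error rates
#'   (defaults 0.015, 0.008).
#' @param length_meanlog,length_sdlog,min_length Read length distribution
#'   (defaults 9.2, 0.35, 500).
#' @return List with `reads` (named character vector), `layout`
#'   (data.frame: read, start, end, strand, identity) and `traces`
#'   (per-read edit traces).
#' @export
simulate_reads <- function(genome, coverage = 40, seed = 1L,
                           model = runlength_error_model(),
                           substitution_rate = 0.015, indel_rate = 0.008,
                           length_meanlog = 9.2, length_sdlog = 0.35,
                           min_length = 500L) {
  L <- nchar(genome)
  with_seed(seed, {
    target <- coverage * L
    lens <- integer(0)
    while (sum(lens) < target) {
      n_more <- max(8L, ceiling((target - sum(lens)) / exp(length_meanlog)))
      new <- pmin(pmax(round(stats::rlnorm(n_more, length_meanlog,
                                           length_sdlog)), min_length), L)
      need <- which(cumsum(as.numeric(new)) >= target - sum(lens))
      if (length(need)) new <- new[seq_len(need[1L])]
      lens <- c(lens, new)
    }
    nr <- length(lens)
    reads <- character(nr)
    traces <- vector("list", nr)
    layout <- data.frame(read = paste0("read_", seq_len(nr)),
                         start = integer(nr), end = integer(nr),
                         strand = character(nr), identity = numeric(nr))
    for (i in seq_len(nr)) {
      len <- lens[i]
      start <- sample.int(L - len + 1L, 1L)
      strand <- if (runif(1) < 0.5) "+" else "-"
      seg <- substr(genome, start, start + len - 1L)
      if (strand == "-") seg <- revcomp(seg)
      tr <- corrupt_read(seg, model, substitution_rate, indel_rate)
      reads[i] <- tr$read
      tr$read <- NULL
      tr$start <- start; tr$end <- start + len - 1L; tr$strand <- strand
      traces[[i]] <- tr
      layout$start[i] <- start; layout$end[i] <- tr$end
      layout$strand[i] <- strand
      layout$identity[i] <- trace_identity(tr, len)
    }
    names(reads) <- layout$read
    list(reads = reads, layout = layout, traces = traces)
  })
}

#' @noRd
corrupt_read <- function(seg, model, substitution_rate, indel_rate) {
  codes <- dna_to_int(seg)
  r <- rle(codes)
  y <- pmin(r$lengths, model$max_len)
  x <- integer(length(y))
  base_chr <- .BASES[r$values + 1L]
  for (b in .BASES) {
    mat <- model$mats[[b]]
    idx_b <- which(base_chr == b)
    for (yy in unique(y[idx_b])) {
      idx <- idx_b[y[idx_b] == yy]
      x[idx] <- sample.int(model$max_len, length(idx), replace = TRUE,
                           prob = mat[yy, ])
    }
  }
  raw2 <- paste0(strrep(base_chr, x), collapse = "")
  chars <- strsplit(raw2, "", fixed = TRUE)[[1L]]
  n2 <- length(chars)
  sub_pos <- which(runif(n2) < substitution_rate)
  sub_base <- .BASES[(dna_to_int(paste0(chars[sub_pos], collapse = "")) +
                        sample.int(3L, length(sub_pos), replace = TRUE)) %% 4L + 1L]
  if (length(sub_pos)) chars[sub_pos] <- sub_base
  del_pos <- which(runif(n2) < indel_rate / 2)
  ins_pos <- which(runif(n2) < indel_rate / 2)
  ins_base <- .BASES[sample.int(4L, length(ins_pos), replace = TRUE)]
  pieces <- chars
  if (length(del_pos)) pieces[del_pos] <- ""
  if (length(ins_pos)) pieces[ins_pos] <- paste0(pieces[ins_pos], ins_base)
  list(read = paste0(pieces, collapse = ""),
       runs = data.frame(base = base_chr, true = r$lengths, obs = x),
       sub_pos = sub_pos, sub_base = sub_base,
       del_pos = del_pos, ins_pos = ins_pos, ins_base = ins_base)
}

#' Replay a read's edit trace against the genome
#'
#' Reconstructs the simulated read exactly from its trace; used to verify
#' that the truth layout is a faithful record.
#'
#' @param genome The genome string the read was simulated from.
#' @param trace One element of `simulate_reads()$traces`.
#' @return The read string.
#' @export
replay_read <- function(genome, trace) {
  seg <- substr(genome, trace$start, trace$end)
  if (trace$strand == "-") seg <- revcomp(seg)
  raw2 <- paste0(strrep(trace$runs$base, trace$runs$obs), collapse = "")
  chars <- strsplit(raw2, "", fixed = TRUE)[[1L]]
  stopifnot(paste0(strrep(trace$runs$base, trace$runs$true), collapse = "") == seg)
  if (length(trace$sub_pos)) chars[trace$sub_pos] <- trace$sub_base
  pieces <- chars
  if (length(trace$del_pos)) pieces[trace$del_pos] <- ""
  if (length(trace$ins_pos))
    pieces[trace$ins_pos] <- paste0(pieces[trace$ins_pos], trace$ins_base)
  paste0(pieces, collapse = "")
}

#' @noRd
trace_identity <- function(tr, true_len) {
  hp_err <- sum(abs(tr$runs$obs - tr$runs$true))
  errors <- length(tr$sub_pos) + length(tr$del_pos) + length(tr$ins_pos) + hp_err
  columns <- true_len + length(tr$ins_pos) + sum(pmax(tr$runs$obs - tr$runs$true, 0))
  1 - errors / columns
}

#' Extract (true, observed) homopolymer length pairs from the truth trace
#'
#' One row per homopolymer of each read's source interval, as used to
#' train the Bayesian run-length model.
#'
#' @param sim Result of [simulate_reads()].
#' @return data.frame with columns `base`, `true`, `obs`.
#' @export
make_runlength_training_pairs <- function(sim) {
  do.call(rbind, lapply(sim$traces, `[[`, "runs"))
}
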