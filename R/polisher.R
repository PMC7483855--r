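#' Bayesian run-length model
#'
#' Per base, a row-normalised matrix of P(observed length x | true length
#' y) with x, y in 1..max_len. Trained from (true, observed) length pairs
#' and used to decode consensus homopolymer lengths from repeated
#' observations, which outperforms simple plurality for long runs where
#' basecallers are systematically dispersed.
#'
#' @param mats Named list (A, C, G, T) of max_len x max_len matrices.
#' @param max_len Matrix size (default 50).
#' @return A `runlength_model`.
#' @export
new_runlength_model <- function(mats, max_len = 50L) {
  stopifnot(all(c("A", "C", "G", "T") %in% names(mats)))
  observed <- lapply(mats, function(m) rowSums(m) > 0)
  structure(list(mats = mats, max_len = as.integer(max_len),
                 observed = observed),
            class = "runlength_model")
}

#' @export
print.runlength_model <- function(x, ...) {
  cat("runlength_model: max_len", x$max_len, "; observed rows:",
      paste(vapply(x$observed, sum, integer(1)), collapse = "/"), "\n")
  invisible(x)
}

#' Train the run-length model from (true, observed) pairs
#'
#' @param pairs data.frame with columns `base`, `true`, `obs` (e.g. from
#'   [make_runlength_training_pairs()], or from alignments of reads to a
#'   trusted reference).
#' @param max_len Matrix size (default 50). Lengths outside 1..max_len
#'   are clamped with a warning.
#' @return A `runlength_model`; rows without observations are flagged.
#' @export
train_runlength_model <- function(pairs, max_len = 50L) {
  if (any(pairs$true < 1L | pairs$true > max_len |
          pairs$obs < 1L | pairs$obs > max_len)) {
    warning("length observations outside [1, max_len] clamped")
    pairs$true <- pmin(pmax(pairs$true, 1L), max_len)
    pairs$obs <- pmin(pmax(pairs$obs, 1L), max_len)
  }
  mats <- lapply(setNames(.BASES, .BASES), function(b) {
    sub <- pairs[pairs$base == b, ]
    m <- matrix(0, max_len, max_len)
    if (nrow(sub)) {
      tab <- table(factor(sub$true, levels = 1:max_len),
                   factor(sub$obs, levels = 1:max_len))
      m <- matrix(as.numeric(tab), max_len, max_len)
      rs <- rowSums(m)
      nz <- rs > 0
      m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
    }
    m
  })
  new_runlength_model(mats, max_len)
}

#' Decode consensus run lengths from repeated observations
#'
#' For each position, the true length maximising the joint log-likelihood
#' of the observed lengths (assumed i.i.d.) is chosen; ties break to the
#' smaller length. Positions where every candidate has zero likelihood
#' fall back to the plurality count with a warning.
#'
#' @param model A `runlength_model`.
#' @param observations List of integer vectors (one per position), or a
#'   single integer vector for one position.
#' @param bases Character vector of the positions' bases.
#' @return Integer vector of decoded lengths.
#' @export
decode_run_lengths <- function(model, observations, bases) {
  if (!is.list(observations)) observations <- list(observations)
  stopifnot(length(bases) == length(observations))
  fell_back <- 0L
  out <- integer(length(observations))
  # floor unseen cells at a small probability so a single outlier
  # observation (e.g. a run interrupted by a substitution) cannot veto
  # an otherwise well-supported length
  floor_p <- log(1e-4)
  logmats <- lapply(model$mats, function(m) {
    lm <- suppressWarnings(log(m)); lm[!is.finite(lm)] <- floor_p; lm
  })
  for (p in seq_along(observations)) {
    x <- pmin(pmax(observations[[p]], 1L), model$max_len)
    lm <- logmats[[bases[p]]]
    cand <- which(model$observed[[bases[p]]])
    if (length(cand)) {
      ll <- rowSums(lm[cand, x, drop = FALSE])
      out[p] <- cand[which.max(ll)]   # which.max takes the first (smaller y)
      next
    }
    fell_back <- fell_back + 1L
    out[p] <- plurality_repeat_count(observations[[p]])
  }
  if (fell_back > 0L)
    warning(sprintf("%d position(s) decoded by plurality fallback", fell_back))
  out
}

#' Write / read a run-length model as CSV
#'
#' One row per (base, true length): `base,true,p1..p[max_len]`.
#'
#' @param model A `runlength_model`.
#' @param path File path.
#' @export
write_runlength_model <- function(model, path) {
  df <- do.call(rbind, lapply(.BASES, function(b) {
    data.frame(base = b, true = seq_len(model$max_len),
               model$mats[[b]], check.names = FALSE)
  }))
  names(df) <- c("base", "true", paste0("p", seq_len(model$max_len)))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_runlength_model
#' @export
read_runlength_model <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE)
  max_len <- nrow(df) / 4L
  mats <- lapply(setNames(.BASES, .BASES), function(b) {
    m <- as.matrix(df[df$base == b, -(1:2)])
    dimnames(m) <- NULL
    m
  })
  new_runlength_model(mats, max_len)
}

#' Pair-HMM parameters for the polisher
#'
#' A standard three-state (match / insertion / deletion) affine-gap
#' pair-HMM over RLE base sequence, conditional on the assembly. The
#' shipped defaults are fixed values chosen so that reads at roughly 90%
#' raw identity align with high posterior mass in RLE space; they can be
#' refitted to other read chemistries.
#'
#' @param trans 3x3 transition matrix (rows from M, I, D; rows sum to 1).
#' @param pm_eq Match-state probability of emitting the assembly base.
#' @param qins Insertion-state emission probability per base (uniform 1/4).
#' @param threshold Posterior sparsity threshold (default 0.01).
#' @param band Band half-width around the guide alignment (default 48).
#' @return A `pairhmm_params` list.
#' @export
pairhmm_params <- function(trans = rbind(c(0.92, 0.04, 0.04),
                                         c(0.75, 0.23, 0.02),
                                         c(0.75, 0.02, 0.23)),
                           pm_eq = 0.96, qins = 0.25, threshold = 0.01,
                           band = 48L) {
  stopifnot(all(abs(rowSums(trans) - 1) < 1e-8), pm_eq > 0, pm_eq < 1)
  structure(list(trans = trans, pm_eq = pm_eq, qins = qins,
                 threshold = threshold, band = as.integer(band)),
            class = "pairhmm_params")
}

#' Polisher parameters
#'
#' @param chunk_size,chunk_boundary Chunked processing: chunk core size
#'   and overlap, in RLE bases (defaults 1000, 50).
#' @param max_depth Per-chunk read downsampling target (default 50).
#' @param candidate_variant_weight Minimum edit weight as a fraction of
#'   windowed coverage (default 0.18).
#' @param column_anchor_trim Backbone nodes must be further than this from
#'   any plausible edit to act as anchors (default 5).
#' @param refinement_loops Extra refinement passes after the first
#'   (default 1).
#' @param max_paths Cap on enumerated alternatives per anchor interval;
#'   regions exceeding it are skipped with a warning (default 64).
#' @return A `polish_params` list.
#' @export
polish_params <- function(chunk_size = 1000L, chunk_boundary = 50L,
                          max_depth = 50L, candidate_variant_weight = 0.18,
                          column_anchor_trim = 5L, refinement_loops = 1L,
                          max_paths = 64L) {
  stopifnot(chunk_boundary < chunk_size, max_depth >= 1,
            candidate_variant_weight > 0, refinement_loops >= 0)
  structure(list(chunk_size = as.integer(chunk_size),
                 chunk_boundary = as.integer(chunk_boundary),
                 max_depth = as.integer(max_depth),
                 candidate_variant_weight = candidate_variant_weight,
                 column_anchor_trim = as.integer(column_anchor_trim),
                 refinement_loops = as.integer(refinement_loops),
                 max_paths = as.integer(max_paths)),
            class = "polish_params")
}

#' Banded pair-HMM alignment posteriors of a read against the assembly
#'
#' Runs the forward-backward algorithm inside a band derived from the
#' guide alignment and keeps the three sparse sets of posterior
#' probabilities (match, insertion, deletion) above the sparsity
#' threshold. Deletion probabilities at the read boundaries are treated
#' as zero. Returns NULL (with a warning) when the band excludes every
#' complete path.
#'
#' @param read_b,asm_b Integer vectors over 0..3 (A,C,G,T) in RLE space.
#' @param guide Two-column matrix of (read position, assembly position)
#'   anchor pairs, 1-based, increasing.
#' @param hmm A [pairhmm_params()] list.
#' @return List with data.frames `match`, `ins`, `del` (columns i, j, p)
#'   and `loglik`, or NULL.
#' @export
compute_alignment_posteriors <- function(read_b, asm_b, guide,
                                         hmm = pairhmm_params()) {
  m <- length(read_b); n <- length(asm_b)
  gx <- c(0, guide[, 1L], m)
  gy <- c(0, guide[, 2L], n)
  o <- order(gx)
  cen <- round(approx(gx[o], gy[o], xout = 0:m, rule = 2, ties = "ordered")$y)
  lo <- pmax(0L, as.integer(cen) - hmm$band)
  hi <- pmin(n, as.integer(cen) + hmm$band)
  res <- .fb_posteriors(read_b, asm_b, as.vector(t(hmm$trans)),
                        hmm$pm_eq, hmm$qins, lo, hi, hmm$threshold)
  if (!is.finite(res$loglik)) {
    warning("band excludes all alignments; read skipped")
    return(NULL)
  }
  res
}

#' Add multi-base indel posteriors by the minimum rule
#'
#' Contiguous runs of stored single-base insertion posteriors at one
#' assembly locus generate multi-base insertion entries whose probability
#' is the minimum over the run (an upper bound on the true probability);
#' deletions are expanded analogously. Entries below the sparsity
#' threshold never spawn multi-base entries because they are not stored.
#'
#' @param ap Posterior set from [compute_alignment_posteriors()].
#' @return `ap` with data.frames `ins_multi` (i1, i2, j, p) and
#'   `del_multi` (i, j1, j2, p) added.
#' @export
expand_multibase_indels <- function(ap) {
  ins <- ap$ins[order(ap$ins$j, ap$ins$i), ]
  im <- list()
  if (nrow(ins)) {
    brk <- cumsum(c(TRUE, diff(ins$i) != 1L | diff(ins$j) != 0L))
    for (g in split(seq_len(nrow(ins)), brk)) {
      Lr <- length(g)
      if (Lr < 2L) next
      for (a in seq_len(Lr - 1L)) {
        pmin_run <- ins$p[g[a]]
        for (b in (a + 1L):Lr) {
          pmin_run <- min(pmin_run, ins$p[g[b]])
          im[[length(im) + 1L]] <- c(ins$i[g[a]], ins$i[g[b]],
                                     ins$j[g[a]], pmin_run)
        }
      }
    }
  }
  ap$ins_multi <- if (length(im)) {
    mm <- do.call(rbind, im)
    data.frame(i1 = mm[, 1L], i2 = mm[, 2L], j = mm[, 3L], p = mm[, 4L])
  } else data.frame(i1 = integer(0), i2 = integer(0), j = integer(0),
                    p = numeric(0))
  del <- ap$del[order(ap$del$i, ap$del$j), ]
  dm <- list()
  if (nrow(del)) {
    brk <- cumsum(c(TRUE, diff(del$j) != 1L | diff(del$i) != 0L))
    for (g in split(seq_len(nrow(del)), brk)) {
      Lr <- length(g)
      if (Lr < 2L) next
      for (a in seq_len(Lr - 1L)) {
        pmin_run <- del$p[g[a]]
        for (b in (a + 1L):Lr) {
          pmin_run <- min(pmin_run, del$p[g[b]])
          dm[[length(dm) + 1L]] <- c(del$i[g[a]], del$j[g[a]],
                                     del$j[g[b]], pmin_run)
        }
      }
    }
  }
  ap$del_multi <- if (length(dm)) {
    mm <- do.call(rbind, dm)
    data.frame(i = mm[, 1L], j1 = mm[, 2L], j2 = mm[, 3L], p = mm[, 4L])
  } else data.frame(i = integer(0), j1 = integer(0), j2 = integer(0),
                    p = numeric(0))
  ap
}

#' Build the weighted partial-order graph
#'
#' The assembly backbone carries, at every node j, a weight w(j, x) for
#' each base x: the expected number of read observations of x aligned to
#' j, summed over all pairwise alignments (so weights may be fractional).
#' Deletion edges and insertion nodes carry the expected number of times
#' the event is seen in the reads. Equivalent indels are left-shifted to
#' their maximal extent and merged with summed weights. A running-window
#' (100-node) coverage estimate is attached.
#'
#' @param asm_b Integer assembly sequence (RLE space).
#' @param posts List of expanded posterior sets, one per read.
#' @param reads_b List of integer read sequences, parallel to `posts`.
#' @return Object of class `weighted_poa`.
#' @export
build_weighted_poa <- function(asm_b, posts, reads_b) {
  n <- length(asm_b)
  w <- matrix(0, 4L, n)
  del_keys <- character(0); del_w <- numeric(0)
  ins_keys <- character(0); ins_w <- numeric(0); ins_j <- integer(0)
  ins_seq <- character(0)
  add_del <- function(j1, j2, p) {
    while (j1 > 1L && asm_b[j1 - 1L] == asm_b[j2]) { j1 <- j1 - 1L; j2 <- j2 - 1L }
    key <- paste(j1, j2)
    hit <- match(key, del_keys)
    if (is.na(hit)) {
      del_keys[length(del_keys) + 1L] <<- key
      del_w[length(del_w) + 1L] <<- p
    } else del_w[hit] <<- del_w[hit] + p
  }
  add_ins <- function(j, seq_b, p) {
    L <- length(seq_b)
    while (j >= 1L && seq_b[L] == asm_b[j]) {
      seq_b <- c(asm_b[j], seq_b[-L]); j <- j - 1L
    }
    if (j < 1L) return(invisible())   # shifted off the chunk start
    key <- paste(j, paste(seq_b, collapse = ""))
    hit <- match(key, ins_keys)
    if (is.na(hit)) {
      ins_keys[length(ins_keys) + 1L] <<- key
      ins_j[length(ins_j) + 1L] <<- j
      ins_seq[length(ins_seq) + 1L] <<- paste(seq_b, collapse = ",")
      ins_w[length(ins_w) + 1L] <<- p
    } else ins_w[hit] <<- ins_w[hit] + p
  }
  for (t in seq_along(posts)) {
    ap <- posts[[t]]
    if (is.null(ap)) next
    mt <- ap$match
    if (nrow(mt)) {
      idx <- (mt$j - 1L) * 4L + reads_b[[t]][mt$i] + 1L
      agg <- rowsum(mt$p, idx)
      w[as.integer(rownames(agg))] <- w[as.integer(rownames(agg))] + agg[, 1L]
    }
    if (nrow(ap$del))
      for (r in seq_len(nrow(ap$del)))
        add_del(ap$del$j[r], ap$del$j[r], ap$del$p[r])
    if (nrow(ap$del_multi))
      for (r in seq_len(nrow(ap$del_multi)))
        add_del(ap$del_multi$j1[r], ap$del_multi$j2[r], ap$del_multi$p[r])
    ins1 <- ap$ins[ap$ins$j >= 1L, , drop = FALSE]
    if (nrow(ins1))
      for (r in seq_len(nrow(ins1)))
        add_ins(ins1$j[r], reads_b[[t]][ins1$i[r]], ins1$p[r])
    if (nrow(ap$ins_multi)) {
      imm <- ap$ins_multi[ap$ins_multi$j >= 1L, , drop = FALSE]
      if (nrow(imm))
        for (r in seq_len(nrow(imm)))
          add_ins(imm$j[r], reads_b[[t]][imm$i1[r]:imm$i2[r]], imm$p[r])
    }
  }
  dels <- if (length(del_keys)) {
    kk <- do.call(rbind, strsplit(del_keys, " "))
    data.frame(j1 = as.integer(kk[, 1L]), j2 = as.integer(kk[, 2L]),
               weight = del_w)
  } else data.frame(j1 = integer(0), j2 = integer(0), weight = numeric(0))
  inss <- data.frame(j = ins_j, seq = ins_seq, weight = ins_w,
                     stringsAsFactors = FALSE)
  tot <- colSums(w)
  cs <- cumsum(c(0, tot))
  hi <- pmin(n, seq_len(n) + 50L); lo <- pmax(0L, seq_len(n) - 51L)
  cov <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  structure(list(asm = asm_b, n = n, w = w, dels = dels, ins = inss,
                 cov = cov),
            class = "weighted_poa")
}

#' @export
print.weighted_poa <- function(x, ...) {
  cat("weighted_poa:", x$n, "backbone nodes,", nrow(x$dels),
      "deletion edges,", nrow(x$ins), "insertion nodes; mean coverage",
      round(mean(x$cov), 1), "\n")
  invisible(x)
}

#' Propose and evaluate local edits to the assembly
#'
#' Edits (substitutions, deletion edges, insertion nodes) with weight
#' below `candidate_variant_weight` times the locally windowed coverage
#' are pruned. Backbone nodes further than `column_anchor_trim` nodes
#' from any remaining plausible edit are anchors; between each pair of
#' successive anchors that brackets at least one edit, all paths through
#' the pruned graph and all plausible substitutions are enumerated (up to
#' `max_paths`; regions over the cap are skipped with a warning). Each
#' alternative is scored by the summed read log-likelihood under the
#' pair-HMM and replaces the original only when strictly more likely, so
#' the accepted likelihood never decreases.
#'
#' @param poa A `weighted_poa`.
#' @param posts Per-read posterior sets (for locating anchor-to-anchor
#'   read substrings).
#' @param reads_b Integer read sequences, parallel to `posts`.
#' @param hmm,params [pairhmm_params()] and [polish_params()].
#' @return List: `asm` (edited integer sequence), `n_edits`,
#'   `n_regions`, `n_skipped`.
#' @export
propose_and_evaluate_edits <- function(poa, posts, reads_b,
                                       hmm = pairhmm_params(),
                                       params = polish_params()) {
  n <- poa$n
  asm <- poa$asm
  thr <- params$candidate_variant_weight * poa$cov
  subs <- which(poa$w >= rep(thr, each = 4L))
  sub_j <- (subs - 1L) %/% 4L + 1L
  sub_x <- (subs - 1L) %% 4L
  keep <- sub_x != asm[sub_j]
  sub_j <- sub_j[keep]; sub_x <- sub_x[keep]
  dels <- poa$dels[poa$dels$weight >= thr[poa$dels$j1], , drop = FALSE]
  inss <- poa$ins[poa$ins$weight >= thr[pmax(poa$ins$j, 1L)], , drop = FALSE]
  touched <- logical(n)
  touched[sub_j] <- TRUE
  tr <- params$column_anchor_trim
  mark <- function(a, b) {
    a <- max(1L, a); b <- min(n, b)
    if (a <= b) touched[a:b] <<- TRUE
  }
  if (nrow(dels)) for (r in seq_len(nrow(dels)))
    mark(dels$j1[r] - 1L, dels$j2[r] + 1L)
  if (nrow(inss)) for (r in seq_len(nrow(inss)))
    mark(inss$j[r], inss$j[r] + 1L)
  if (!any(touched))
    return(list(asm = asm, origin = seq_len(n), n_edits = 0L,
                n_regions = 0L, n_skipped = 0L))
  bad <- logical(n)
  for (j in which(touched)) bad[max(1L, j - tr):min(n, j + tr)] <- TRUE
  anchors <- unique(c(1L, which(!bad), n))
  anchors <- sort(anchors)
  sub_by_j <- split(sub_x, factor(sub_j, levels = seq_len(n)))
  del_by_j <- if (nrow(dels))
    split(seq_len(nrow(dels)), factor(dels$j1, levels = seq_len(n)))
  else NULL
  ins_by_j <- if (nrow(inss))
    split(seq_len(nrow(inss)), factor(inss$j, levels = seq_len(n)))
  else NULL
  ins_seqs <- lapply(strsplit(inss$seq, ","), as.integer)

  enumerate_region <- function(a, b) {
    out <- list()
    over <- FALSE
    emit <- function(x) {
      if (length(out) >= params$max_paths) { over <<- TRUE; return() }
      out[[length(out) + 1L]] <<- x
    }
    step <- function(j, acc) {
      if (over) return()
      # acc holds sequence up to and including node j's base
      if (j == b) { emit(acc); return() }
      # optional insertion after j
      ins_here <- if (!is.null(ins_by_j)) ins_by_j[[j]] else integer(0)
      nexts <- list(list(acc2 = acc))
      for (r in ins_here)
        nexts[[length(nexts) + 1L]] <- list(acc2 = c(acc, ins_seqs[[r]]))
      for (nx in nexts) {
        # advance to j+1, or jump a deletion starting at j+1
        jn <- j + 1L
        for (base in c(asm[jn], sub_by_j[[jn]])) {
          if (jn == b && base != asm[jn]) next   # anchors are fixed
          step(jn, c(nx$acc2, base))
        }
        del_here <- if (!is.null(del_by_j)) del_by_j[[jn]] else integer(0)
        for (r in del_here) {
          j2 <- dels$j2[r]
          if (j2 >= b) next
          jn2 <- j2 + 1L
          for (base in c(asm[jn2], sub_by_j[[jn2]])) {
            if (jn2 == b && base != asm[jn2]) next
            step(jn2, c(nx$acc2, base))
          }
        }
      }
    }
    step(a, asm[a])
    if (over) NULL else out
  }

  # per read: highest-posterior aligned read position for each backbone
  # node (0 = none stored)
  best_i <- lapply(posts, function(ap) {
    if (is.null(ap)) return(NULL)
    mt <- ap$match[order(ap$match$j, -ap$match$p), ]
    mt <- mt[!duplicated(mt$j), ]
    bi <- integer(n)
    bi[mt$j] <- mt$i
    bi
  })
  n_edits <- 0L; n_regions <- 0L; n_skipped <- 0L
  replacements <- list()
  for (t in seq_len(length(anchors) - 1L)) {
    a <- anchors[t]; b <- anchors[t + 1L]
    if (b <= a || !any(touched[a:b])) next
    n_regions <- n_regions + 1L
    if (b - a > 100L) { n_skipped <- n_skipped + 1L; next }
    # too little read evidence to adjudicate edits: keep the draft
    if (mean(poa$cov[a:b]) < 4) next
    cands <- enumerate_region(a, b)
    if (is.null(cands)) { n_skipped <- n_skipped + 1L; next }
    orig <- asm[a:b]
    keys <- vapply(cands, paste, "", collapse = ",")
    okey <- paste(orig, collapse = ",")
    if (!(okey %in% keys)) { cands <- c(list(orig), cands); keys <- c(okey, keys) }
    cands <- cands[!duplicated(keys)]
    keys <- keys[!duplicated(keys)]
    if (length(cands) < 2L) next
    # read substrings between the anchors (precomputed best matches)
    subs_reads <- list()
    for (rt in seq_along(posts)) {
      bi <- best_i[[rt]]
      if (is.null(bi)) next
      ia <- bi[a]; ib <- bi[b]
      if (ia == 0L || ib == 0L || ib <= ia) next
      subs_reads[[length(subs_reads) + 1L]] <- reads_b[[rt]][ia:ib]
    }
    if (!length(subs_reads)) next
    trv <- as.vector(t(hmm$trans))
    scores <- vapply(cands, function(cd) {
      sum(vapply(subs_reads, function(rb)
        .forward_loglik(rb, cd, trv, hmm$pm_eq, hmm$qins), numeric(1)))
    }, numeric(1))
    oi <- match(okey, keys)
    best <- which.max(scores)
    if (scores[best] > scores[oi] + 1e-9 && best != oi) {
      n_edits <- n_edits + 1L
      replacements[[length(replacements) + 1L]] <-
        list(a = a, b = b, seq = cands[[best]])
    }
  }
  if (n_skipped > 0L)
    warning(sprintf("%d region(s) skipped: too many alternative paths",
                    n_skipped))
  origin <- seq_len(n)
  if (length(replacements)) {
    replacements <- replacements[order(vapply(replacements, `[[`, integer(1),
                                              "a"))]
    pieces <- list(); opieces <- list()
    cur <- 1L
    for (rp in replacements) {
      if (rp$a >= cur) {
        pieces[[length(pieces) + 1L]] <- asm[cur:rp$a]
        opieces[[length(opieces) + 1L]] <- cur:rp$a
      }
      # interior replacement: anchors stay, interior comes from the winner
      interior <- rp$seq[-c(1L, length(rp$seq))]
      pieces[[length(pieces) + 1L]] <- interior
      opieces[[length(opieces) + 1L]] <- rep(NA_integer_, length(interior))
      cur <- rp$b
    }
    pieces[[length(pieces) + 1L]] <- asm[cur:n]
    opieces[[length(opieces) + 1L]] <- cur:n
    asm <- unlist(pieces, use.names = FALSE)
    origin <- unlist(opieces, use.names = FALSE)
  }
  list(asm = asm, origin = origin, n_edits = n_edits,
       n_regions = n_regions, n_skipped = n_skipped)
}

#' Map reads onto a draft assembly in marker space
#'
#' Aligns each read (better of the two orientations) against the assembly
#' using the same marker machinery as the assembler, producing per-read
#' guide anchors in RLE coordinates for the polisher's banding.
#'
#' @param asm_rle Assembly `rle_seq`.
#' @param reads_rle List of read `rle_seq` (forward orientation).
#' @param k,probability,seed Marker selection for the mapping (defaults
#'   10, 0.1, 1).
#' @param min_aligned Minimum aligned markers to accept a mapping
#'   (default 10).
#' @return List per read: NULL if unmapped, else list(`strand`, `guide`)
#'   where guide is a two-column matrix of (read RLE pos, assembly RLE
#'   pos) anchors for the oriented read.
#' @export
map_reads_to_assembly <- function(asm_rle, reads_rle, k = 10L,
                                  probability = 0.1, seed = 1L,
                                  min_aligned = 10L) {
  ms <- select_markers(k, probability, seed)
  mk_asm <- find_markers(asm_rle, ms)
  ap <- align_params(min_aligned_marker_count = min_aligned)
  lapply(reads_rle, function(rr) {
    mf <- find_markers(rr, ms)
    mr <- marker_seq_revcomp(mf, ms)
    af <- align_markers(mf, mk_asm, ap)
    ar <- align_markers(mr, mk_asm, ap)
    use_f <- af$aligned_count >= ar$aligned_count
    al <- if (use_f) af else ar
    mk <- if (use_f) mf else mr
    if (!al$accepted) return(NULL)
    list(strand = if (use_f) "+" else "-",
         guide = cbind(mk$pos[al$pairs[, 1L]], mk_asm$pos[al$pairs[, 2L]]))
  })
}

#' @noRd
polish_chunk <- function(asm_b, read_subs, guides, hmm, params) {
  asm_cur <- asm_b
  posts <- NULL
  loops <- 1L + params$refinement_loops
  origin <- seq_along(asm_b)   # current coord -> original coord (NA = new)
  offmap <- seq_along(asm_b)   # original coord -> current coord
  # each read is aligned only against its guide-projected window of the
  # chunk; posteriors are shifted back into chunk coordinates
  read_posteriors <- function(asm_now) {
    n_now <- length(asm_now)
    lapply(seq_along(read_subs), function(t) {
      g <- guides[[t]]
      g2 <- cbind(g[, 1L], offmap[pmin(g[, 2L], length(offmap))])
      j1 <- max(1L, min(g2[, 2L]) - 30L)
      j2 <- min(n_now, max(g2[, 2L]) + 30L)
      if (j2 - j1 < 10L) return(NULL)
      gl <- cbind(g2[, 1L], g2[, 2L] - j1 + 1L)
      ap <- suppressWarnings(
        compute_alignment_posteriors(read_subs[[t]], asm_now[j1:j2], gl, hmm))
      if (is.null(ap)) return(NULL)
      ap$match$j <- ap$match$j + j1 - 1L
      ap$ins$j <- ap$ins$j + j1 - 1L
      ap$del$j <- ap$del$j + j1 - 1L
      ap
    })
  }
  for (loop in seq_len(loops)) {
    posts <- read_posteriors(asm_cur)
    posts <- lapply(posts, function(ap)
      if (is.null(ap)) NULL else expand_multibase_indels(ap))
    poa <- build_weighted_poa(asm_cur, posts, read_subs)
    res <- propose_and_evaluate_edits(poa, posts, read_subs, hmm, params)
    if (res$n_edits == 0L) { asm_cur <- res$asm; break }
    origin <- origin[res$origin]
    # original -> current map from the origin track, gaps interpolated
    omap <- rep(NA_real_, length(asm_b))
    known <- which(!is.na(origin))
    omap[origin[known]] <- known
    offmap <- round(approx(seq_along(asm_b), omap,
                           xout = seq_along(asm_b), rule = 2)$y)
    offmap[is.na(offmap)] <- 1L
    offmap <- pmin(pmax(offmap, 1L), length(res$asm))
    asm_cur <- res$asm
    if (loop == loops) {
      # recompute posteriors against the final sequence for RL decoding
      posts <- read_posteriors(asm_cur)
    }
  }
  list(asm = asm_cur, origin = origin, posts = posts)
}

#' @noRd
chunk_runlength_obs <- function(asm_b, posts, sub_counts) {
  n <- length(asm_b)
  obs <- vector("list", n)
  for (t in seq_along(posts)) {
    ap <- posts[[t]]
    if (is.null(ap)) next
    mt <- ap$match
    if (!nrow(mt)) next
    # best-supported read position per backbone node, same base only
    mt <- mt[order(mt$j, -mt$p), ]
    mt <- mt[!duplicated(mt$j), ]
    same <- sub_counts$bases[[t]][mt$i] == asm_b[mt$j]
    mt <- mt[same & mt$p >= 0.1, ]
    if (!nrow(mt)) next
    for (r in seq_len(nrow(mt)))
      obs[[mt$j[r]]] <- c(obs[[mt$j[r]]], sub_counts$counts[[t]][mt$i[r]])
  }
  obs
}

#' @noRd
stitch_rle <- function(left, right, overlap_est) {
  take <- min(length(left$bases), overlap_est + 30L)
  give <- min(length(right$bases), overlap_est + 30L)
  ls <- int_to_dna(left$bases[(length(left$bases) - take + 1L):length(left$bases)])
  rs <- int_to_dna(right$bases[seq_len(give)])
  pa <- Biostrings::pairwiseAlignment(ls, rs, type = "global",
                                      gapOpening = 4, gapExtension = 1)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  is_match <- ap == as_ & ap != "-"
  r <- rle(is_match)
  ends <- cumsum(r$lengths)
  runs <- which(r$values)
  if (!length(runs)) {
    # no agreement: butt-join at the estimated overlap
    lkeep <- length(left$bases) - overlap_est %/% 2L
    rfrom <- overlap_est - overlap_est %/% 2L + 1L
  } else {
    best <- runs[which.max(r$lengths[runs])]
    mid_col <- ends[best] - r$lengths[best] %/% 2L
    lpos <- cumsum(ap != "-")[mid_col]     # position within ls
    rpos <- cumsum(as_ != "-")[mid_col]    # position within rs
    lkeep <- length(left$bases) - take + lpos
    rfrom <- rpos + 1L
  }
  bases <- c(left$bases[seq_len(lkeep)],
             right$bases[rfrom:length(right$bases)])
  counts <- c(left$counts[seq_len(lkeep)],
              right$counts[rfrom:length(right$bases)])
  # splice may abut equal bases; re-collapse to keep the RLE invariant
  nb <- length(bases)
  if (nb > 1L) {
    dup <- which(bases[-1L] == bases[-nb]) + 1L
    if (length(dup)) {
      counts[dup - 1L] <- counts[dup - 1L] + counts[dup]
      bases <- bases[-dup]; counts <- counts[-dup]
    }
  }
  list(bases = bases, counts = counts)
}

#' Polish an assembly with chunked pair-HMM refinement
#'
#' The assembly and reads are run-length encoded; the assembly is split
#' into chunks (default 1000 RLE bases with 50-base overlaps), reads in
#' each chunk are downsampled towards `max_depth` using the
#' `1 - (chunkSize + 2*chunkBoundary) * maxDepth / N_c` discard
#' probability, and each chunk is refined by weighted-POA edit proposal
#' and likelihood evaluation (optionally looping). Neighbouring polished
#' chunks are stitched at the middle of the longest identical run of an
#' alignment of their overlaps. Finally, repeat counts are decoded with
#' the Bayesian run-length model (plurality where the model has no
#' information) and the raw polished sequence is emitted.
#'
#' @param assembly Draft assembly (raw DNA string).
#' @param reads Named character vector of reads.
#' @param model A `runlength_model`, or NULL for plurality decoding.
#' @param hmm,params [pairhmm_params()] and [polish_params()].
#' @param seed Integer seed (chunk downsampling).
#' @param mappings Optional precomputed [map_reads_to_assembly()] result;
#'   computed internally when NULL.
#' @param verbose Log progress.
#' @return List: `polished` (raw string), `rle` (bases/counts), `stats`.
#' @export
polish_assembly <- function(assembly, reads, model = NULL,
                            hmm = pairhmm_params(), params = polish_params(),
                            seed = 1L, mappings = NULL, verbose = FALSE) {
  log_ <- function(...) if (verbose) message(sprintf(...))
  asm_rle <- rle_encode(assembly)
  asm_b <- dna_to_int(asm_rle$bases)
  n <- length(asm_b)
  reads_rle <- lapply(reads, rle_encode)
  if (is.null(mappings))
    mappings <- map_reads_to_assembly(asm_rle, reads_rle, seed = seed)
  oriented <- lapply(seq_along(reads_rle), function(i) {
    if (is.null(mappings[[i]])) return(NULL)
    rr <- if (mappings[[i]]$strand == "+") reads_rle[[i]]
          else rle_revcomp(reads_rle[[i]])
    list(b = dna_to_int(rr$bases), counts = rr$counts,
         guide = mappings[[i]]$guide)
  })
  mapped <- which(!vapply(oriented, is.null, TRUE))
  log_("mapped reads: %d / %d", length(mapped), length(reads))

  starts <- seq(1L, n, by = params$chunk_size)
  chunks <- vector("list", length(starts))
  stats <- list(chunks = length(starts), edits = 0L, skipped = 0L,
                unpolished_chunks = 0L)
  for (ci in seq_along(starts)) {
    s <- starts[ci]
    core_end <- min(n, s + params$chunk_size - 1L)
    ext_s <- max(1L, s - params$chunk_boundary)
    ext_e <- min(n, core_end + params$chunk_boundary)
    chunk_b <- asm_b[ext_s:ext_e]
    nc_len <- ext_e - ext_s + 1L
    subs <- list(); gds <- list(); scounts <- list(bases = list(),
                                                  counts = list())
    for (t in mapped) {
      ort <- oriented[[t]]
      g <- ort$guide
      span <- range(g[, 2L])
      if (span[1L] > ext_e || span[2L] < ext_s) next
      rpos <- round(approx(g[, 2L], g[, 1L], xout = c(ext_s, ext_e),
                           rule = 2, ties = "ordered")$y)
      i1 <- max(1L, rpos[1L]); i2 <- min(length(ort$b), rpos[2L])
      if (i2 - i1 + 1L < 20L) next
      ganch <- g[g[, 2L] >= ext_s & g[, 2L] <= ext_e &
                   g[, 1L] >= i1 & g[, 1L] <= i2, , drop = FALSE]
      if (nrow(ganch) < 2L) next
      subs[[length(subs) + 1L]] <- ort$b[i1:i2]
      scounts$bases[[length(subs)]] <- ort$b[i1:i2]
      scounts$counts[[length(subs)]] <- ort$counts[i1:i2]
      gds[[length(gds) + 1L]] <- cbind(ganch[, 1L] - i1 + 1L,
                                       ganch[, 2L] - ext_s + 1L)
    }
    if (!length(subs)) {
      stats$unpolished_chunks <- stats$unpolished_chunks + 1L
      warning(sprintf("chunk %d has no mapped reads; emitted unpolished", ci))
      chunks[[ci]] <- list(bases = chunk_b,
                           counts = asm_rle$counts[ext_s:ext_e],
                           ext_s = ext_s, ext_e = ext_e)
      next
    }
    n_c <- sum(lengths(subs))
    p_keep <- (params$chunk_size + 2L * params$chunk_boundary) *
      params$max_depth / n_c
    if (p_keep < 1) {
      keep <- with_seed(derive_seed(seed, 500L + ci),
                        runif(length(subs)) < p_keep)
      if (!any(keep)) keep[1L] <- TRUE
      subs <- subs[keep]
      gds <- gds[keep]
      scounts$bases <- scounts$bases[keep]
      scounts$counts <- scounts$counts[keep]
    }
    pc <- polish_chunk(chunk_b, subs, gds, hmm, params)
    obs <- chunk_runlength_obs(pc$asm, pc$posts, scounts)
    counts <- integer(length(pc$asm))
    # re-decode where at least five informative observations exist;
    # elsewhere keep the draft repeat count (the thin ends of a contig
    # see only a couple of reads, whose raw lengths are noisier than
    # the draft)
    draft_counts <- asm_rle$counts[ext_s:ext_e]
    decode_pos <- lengths(obs) >= 5L
    if (any(decode_pos)) {
      bch <- .BASES[pc$asm[decode_pos] + 1L]
      counts[decode_pos] <- if (is.null(model))
        vapply(obs[decode_pos], plurality_repeat_count, integer(1))
      else suppressWarnings(decode_run_lengths(model, obs[decode_pos], bch))
    }
    rest <- which(!decode_pos)
    for (p in rest) {
      counts[p] <- if (!is.na(pc$origin[p])) draft_counts[pc$origin[p]]
      else if (length(obs[[p]])) plurality_repeat_count(obs[[p]])
      else 1L
    }
    chunks[[ci]] <- list(bases = pc$asm, counts = counts,
                         ext_s = ext_s, ext_e = ext_e)
    log_("chunk %d/%d: %d reads, %d RLE bases", ci, length(starts),
         length(subs), length(pc$asm))
  }
  cur <- chunks[[1L]]
  if (length(chunks) > 1L) {
    for (ci in 2L:length(chunks)) {
      ov <- cur$ext_e - chunks[[ci]]$ext_s + 1L
      cur2 <- stitch_rle(cur, chunks[[ci]], max(10L, ov))
      cur2$ext_s <- cur$ext_s; cur2$ext_e <- chunks[[ci]]$ext_e
      cur <- cur2
    }
  }
  polished <- paste0(strrep(.BASES[cur$bases + 1L], pmax(cur$counts, 1L)),
                     collapse = "")
  list(polished = polished,
       rle = list(bases = int_to_dna(cur$bases), counts = cur$counts),
       stats = stats)
}

#' Convert SAM alignments into polisher mappings
#'
#' Builds the same per-read guide structure as
#' [map_reads_to_assembly()] from an external read-to-assembly SAM file
#' (see [read_sam()]), converting raw-base CIGAR anchors into RLE
#' coordinates. SAM's 1-based convention is honoured at the boundary.
#'
#' @param sam data.frame from [read_sam()].
#' @param reads Named character vector of reads (as given to the
#'   polisher; reads aligned on the reverse strand are handled through
#'   their stored orientation).
#' @param assembly Assembly string the reads were aligned to.
#' @return List parallel to `reads`: NULL or list(`strand`, `guide`).
#' @export
sam_mappings <- function(sam, reads, assembly) {
  asm_rle <- rle_encode(assembly)
  asm_map <- rep(seq_along(asm_rle$counts), asm_rle$counts)
  lapply(names(reads), function(nm) {
    row <- which(sam$qname == nm)
    if (!length(row)) return(NULL)
    row <- row[1L]
    oriented <- if (sam$strand[row] == "-") revcomp(reads[[nm]])
                else reads[[nm]]
    r_rle <- rle_encode(oriented)
    r_map <- rep(seq_along(r_rle$counts), r_rle$counts)
    q <- pmin(sam$qpos[[row]], length(r_map))
    r <- pmin(sam$rpos[[row]], length(asm_map))
    g <- unique(cbind(r_map[q], asm_map[r]))
    g <- g[order(g[, 1L]), , drop = FALSE]
    keep <- !duplicated(g[, 1L]) & !duplicated(g[, 2L]) &
      c(TRUE, diff(g[, 2L]) > 0)
    g <- g[keep, , drop = FALSE]
    if (nrow(g) < 2L) return(NULL)
    list(strand = sam$strand[row], guide = g)
  })
}
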