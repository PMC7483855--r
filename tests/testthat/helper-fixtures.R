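# Shared fixtures and independent oracles used across the suite.

rand_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# The worked two-read example: reads a-b-c-d-e and a-b-x-d-e in marker
# space, built from real sequence so every layer runs on it.
make_toy_reads <- function() {
  mk <- c(a = "ACA", b = "CTC", c = "TAT", d = "CAT", e = "ATA", x = "TCA")
  rc <- vapply(mk, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, "")
  ms <- marker_set(sort(unique(c(mk, rc))))
  sep <- "CG"
  r1 <- paste(mk[c("a", "b", "c", "d", "e")], collapse = sep)
  r2 <- paste(mk[c("a", "b", "x", "d", "e")], collapse = sep)
  id_of <- function(km) unname(ms$ids[match(km, ms$members)])
  list(ms = ms, mk = mk, r1 = r1, r2 = r2, id_of = id_of)
}

make_toy_marker_graph <- function(min_coverage = 1L) {
  toy <- make_toy_reads()
  rl <- list(rle_encode(toy$r1), rle_encode(toy$r2))
  mf <- lapply(rl, find_markers, ms = toy$ms)
  mr <- lapply(mf, marker_seq_revcomp, ms = toy$ms)
  al <- align_markers(mf[[1]], mf[[2]], align_params(min_aligned_marker_count = 1))
  mg <- build_marker_graph(rl, mf, mr,
                           list(list(r1 = 1L, r2 = 2L, same_strand = TRUE,
                                     pairs = al$pairs)),
                           min_coverage = min_coverage, max_coverage = 100L,
                           k = 3L)
  c(toy, list(mg = mg, alignment = al))
}

# Synthetic marker graph from a bare edge list, for the simplification
# operators (no strand mirror: rc_edge all NA).
toy_mg <- function(v0, v1, coverage = rep(1L, length(v0)),
                   nv = max(c(v0, v1)), skip1 = rep(0L, length(v0))) {
  ed <- data.table::data.table(e = seq_along(v0), v0 = as.integer(v0),
                               v1 = as.integer(v1),
                               coverage = as.integer(coverage),
                               skip1 = as.integer(skip1), removed = FALSE)
  structure(list(k = 3L, n_reads = 0L,
                 vertices = data.table::data.table(v = seq_len(nv)),
                 edges = ed, rc_edge = rep(NA_integer_, nrow(ed))),
            class = "marker_graph")
}

alive_edges <- function(mg) mg$edges[!mg$edges$removed, ]

# Independent constrained-chain oracle: optimal (count, total skip) by
# direct quadratic DP over match cells, same constraints as the
# implementation (per-read skip bound; per-end trim bound taken as the
# minimum over the two reads).
oracle_chain <- function(a, b, max_skip, max_trim) {
  cells <- which(outer(a, b, "=="), arr.ind = TRUE)
  if (nrow(cells) == 0L) return(list(count = 0L, skip = 0L))
  cells <- cells[order(cells[, 1L], cells[, 2L]), , drop = FALSE]
  M <- nrow(cells)
  na <- length(a); nb <- length(b)
  cnt <- rep(-1L, M); skp <- rep(0L, M)
  for (c0 in seq_len(M)) {
    i <- cells[c0, 1L]; j <- cells[c0, 2L]
    if (min(i, j) - 1L <= max_trim) { cnt[c0] <- 1L; skp[c0] <- 0L }
    if (c0 > 1L) for (p in seq_len(c0 - 1L)) {
      if (cnt[p] <= 0L) next
      ip <- cells[p, 1L]; jp <- cells[p, 2L]
      if (ip >= i || jp >= j) next
      if (i - ip - 1L > max_skip || j - jp - 1L > max_skip) next
      ncand <- cnt[p] + 1L
      scand <- skp[p] + (i - ip - 1L) + (j - jp - 1L)
      if (ncand > cnt[c0] || (ncand == cnt[c0] && scand < skp[c0])) {
        cnt[c0] <- ncand; skp[c0] <- scand
      }
    }
  }
  ends <- which(cnt > 0L &
                  pmin(na - cells[, 1L], nb - cells[, 2L]) <= max_trim)
  if (!length(ends)) return(list(count = 0L, skip = 0L))
  best <- ends[order(-cnt[ends], skp[ends])][1L]
  list(count = cnt[best], skip = skp[best])
}

# Check a chain against the banding constraints directly.
chain_is_valid <- function(pairs, na, nb, max_skip, max_trim) {
  if (nrow(pairs) == 0L) return(FALSE)
  i <- pairs[, 1L]; j <- pairs[, 2L]
  ok <- all(diff(i) > 0L) && all(diff(j) > 0L)
  if (nrow(pairs) > 1L)
    ok <- ok && all(diff(i) - 1L <= max_skip) && all(diff(j) - 1L <= max_skip)
  ok && min(i[1L], j[1L]) - 1L <= max_trim &&
    min(na - i[nrow(pairs)], nb - j[nrow(pairs)]) <= max_trim
}

# Independent full (unbanded) forward-backward oracle in plain R.
r_forward_backward <- function(r, s, trans, pm_eq, qins) {
  m <- length(r); n <- length(s)
  lt <- log(trans); lq <- log(qins)
  em <- function(i, j) if (r[i] == s[j]) log(pm_eq) else log((1 - pm_eq) / 3)
  lse <- function(x) { mx <- max(x); if (!is.finite(mx)) -Inf else mx + log(sum(exp(x - mx))) }
  NEG <- -Inf
  fM <- matrix(NEG, m + 1, n + 1); fX <- fM; fY <- fM
  fM[1, 1] <- 0
  for (i in 0:m) for (j in 0:n) {
    if (i > 0 && j > 0)
      fM[i + 1, j + 1] <- em(i, j) + lse(c(fM[i, j] + lt[1, 1],
                                           fX[i, j] + lt[2, 1],
                                           fY[i, j] + lt[3, 1]))
    if (i > 0)
      fX[i + 1, j + 1] <- lq + lse(c(fM[i, j + 1] + lt[1, 2],
                                     fX[i, j + 1] + lt[2, 2],
                                     fY[i, j + 1] + lt[3, 2]))
    if (j > 0)
      fY[i + 1, j + 1] <- lse(c(fM[i + 1, j] + lt[1, 3],
                                fX[i + 1, j] + lt[2, 3],
                                fY[i + 1, j] + lt[3, 3]))
  }
  total <- lse(c(fM[m + 1, n + 1], fX[m + 1, n + 1], fY[m + 1, n + 1]))
  bM <- matrix(NEG, m + 1, n + 1); bX <- bM; bY <- bM
  bM[m + 1, n + 1] <- bX[m + 1, n + 1] <- bY[m + 1, n + 1] <- 0
  for (i in m:0) for (j in n:0) {
    if (i == m && j == n) next
    acc <- function(from) {
      v <- NEG
      if (i < m && j < n)
        v <- lse(c(v, lt[from, 1] + em(i + 1, j + 1) + bM[i + 2, j + 2]))
      if (i < m)
        v <- lse(c(v, lt[from, 2] + lq + bX[i + 2, j + 1]))
      if (j < n)
        v <- lse(c(v, lt[from, 3] + bY[i + 1, j + 2]))
      v
    }
    bM[i + 1, j + 1] <- acc(1); bX[i + 1, j + 1] <- acc(2)
    bY[i + 1, j + 1] <- acc(3)
  }
  list(loglik = total,
       match = exp(fM[-1, -1, drop = FALSE] + bM[-1, -1, drop = FALSE] - total),
       ins = exp(fX[-1, , drop = FALSE] + bX[-1, , drop = FALSE] - total),
       del = exp(fY[, -1, drop = FALSE] + bY[, -1, drop = FALSE] - total))
}

# Bounded-horizon reachability over the alive edges of a marker graph.
reach_within <- function(mg, maxd) {
  ed <- alive_edges(mg)
  nv <- nrow(mg$vertices)
  out <- split(ed$v1, factor(ed$v0, levels = seq_len(nv)))
  reach <- matrix(FALSE, nv, nv)
  for (v in seq_len(nv)) {
    frontier <- v
    seen <- v
    for (d in seq_len(maxd)) {
      nxt <- setdiff(unique(unlist(out[frontier], use.names = FALSE)), seen)
      if (!length(nxt)) break
      reach[v, nxt] <- TRUE
      seen <- c(seen, nxt)
      frontier <- nxt
    }
  }
  reach
}
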