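#' Candidate overlap detection by threshold MinHash ("low hash")
#'
#' Classical MinHash finds pairs with high Jaccard similarity, which
#' penalises exact containments of a short read in a long one (their
#' Jaccard index is only the length ratio). The low-hash variant instead
#' keeps, in every iteration, *all* features whose hash falls below a
#' threshold fraction, storing an oriented read in one bucket per low
#' hash. The expected number of low hashes grows with read length, which
#' removes the short/long bias. Features are windows of m consecutive
#' marker ids.
#'
#' @param m Feature width in markers (default 4).
#' @param hash_fraction Fraction of hash space that counts as low
#'   (default 0.01).
#' @param iterations Number of hash iterations (default 10).
#' @param max_bucket_size Buckets with more occupants are ignored
#'   (default 10), mitigating common repeats.
#' @param min_frequency Minimum number of iterations in which a pair must
#'   be co-bucketed to be reported (default 2).
#' @param seed Integer seed for the per-iteration hash salts.
#' @return A `lowhash_params` list.
#' @export
lowhash_params <- function(m = 4L, hash_fraction = 0.01, iterations = 10L,
                           max_bucket_size = 10L, min_frequency = 2L,
                           seed = 1L) {
  stopifnot(m >= 1, hash_fraction > 0, hash_fraction <= 1, iterations >= 1,
            max_bucket_size >= 1, min_frequency >= 1)
  structure(list(m = as.integer(m), hash_fraction = hash_fraction,
                 iterations = as.integer(iterations),
                 max_bucket_size = as.integer(max_bucket_size),
                 min_frequency = as.integer(min_frequency),
                 seed = as.integer(seed)),
            class = "lowhash_params")
}

#' Extract MinHash features from a marker id sequence
#'
#' @param ids Integer vector of marker ids (or a `marker_seq`).
#' @param m Feature width.
#' @return Integer matrix with one row per feature of `m` consecutive ids;
#'   `max(0, length - m + 1)` rows.
#' @export
extract_features <- function(ids, m) {
  if (inherits(ids, "marker_seq")) ids <- ids$ids
  n <- length(ids)
  if (n < m) return(matrix(integer(0), nrow = 0, ncol = m))
  nf <- n - m + 1L
  mat <- vapply(seq_len(m), function(j) ids[j:(j + nf - 1L)], integer(nf))
  if (nf == 1L) mat <- matrix(mat, nrow = 1L)
  mat
}

#' Jaccard similarity of two feature sets
#'
#' @param a,b Feature sets: vectors, or matrices with one feature per row.
#' @return `|A intersect B| / |A union B|`; 0 when both sets are empty.
#' @export
jaccard <- function(a, b) {
  key <- function(x) {
    if (is.matrix(x)) apply(x, 1L, paste, collapse = ",") else as.character(x)
  }
  a <- unique(key(a)); b <- unique(key(b))
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' One low-hash iteration: bucket oriented reads by low-hash features
#'
#' A fresh hash function (salted from the seed and the iteration number)
#' maps each feature to \[0, 1); an oriented read enters the bucket of
#' every feature hashing below `hash_fraction`. The bucket key is the
#' hash value itself.
#'
#' @param marker_ids List of integer marker-id vectors, one per oriented
#'   read.
#' @param params A `lowhash_params`.
#' @param iteration 0-based iteration number (`< params$iterations`).
#' @return A `data.table` with columns `bucket` (hash value) and `item`
#'   (oriented-read index), unique per (item, bucket).
#' @export
lowhash_pass <- function(marker_ids, params, iteration) {
  stopifnot(iteration >= 0, iteration < params$iterations)
  salt <- derive_seed(params$seed, 1000 + iteration)
  res <- lapply(seq_along(marker_ids), function(i) {
    h <- .feature_hashes(marker_ids[[i]], params$m, salt)
    h[h < params$hash_fraction]
  })
  n <- lengths(res)
  dt <- data.table::data.table(bucket = unlist(res),
                               item = rep(seq_along(marker_ids), n))
  unique(dt, by = c("item", "bucket"))
}

#' Find candidate overlapping oriented-read pairs
#'
#' Aggregates co-bucketing events over all iterations (a pair counts at
#' most once per iteration), keeps pairs seen at least `min_frequency`
#' times, and reports them in canonical strand-symmetric form: a pairing
#' of read `a` forward with read `b` forward (`same_strand = TRUE`)
#' represents equally the reverse pairing of both complements.
#'
#' @param markers_fwd,markers_rev Lists of integer marker-id vectors for
#'   each read's forward and reverse-complement orientation.
#' @param params A `lowhash_params`.
#' @return data.frame with columns `r1 < r2`, `same_strand`, `frequency`.
#' @export
find_candidate_pairs <- function(markers_fwd, markers_rev, params) {
  nr <- length(markers_fwd)
  stopifnot(length(markers_rev) == nr)
  # oriented read o: reads 1..nr forward, nr+1..2nr reverse
  oriented <- c(markers_fwd, markers_rev)
  acc <- vector("list", params$iterations)
  for (it in seq_len(params$iterations) - 1L) {
    dt <- lowhash_pass(oriented, params, it)
    if (nrow(dt) == 0L) next
    dt <- dt[, if (.N >= 2L && .N <= params$max_bucket_size)
      list(a = rep(item, each = .N)[upper.tri(diag(.N))],
           b = rep(item, .N)[upper.tri(diag(.N))]), by = "bucket"]
    if (nrow(dt) == 0L) next
    ra <- (dt$a - 1L) %% nr + 1L; sa <- dt$a > nr
    rb <- (dt$b - 1L) %% nr + 1L; sb <- dt$b > nr
    keep <- ra != rb
    r1 <- pmin(ra, rb)[keep]
    r2 <- pmax(ra, rb)[keep]
    same <- (sa == sb)[keep]
    acc[[it + 1L]] <- unique(data.table::data.table(r1 = r1, r2 = r2,
                                                    same_strand = same))
  }
  all <- data.table::rbindlist(acc)
  if (nrow(all) == 0L)
    return(data.frame(r1 = integer(0), r2 = integer(0),
                      same_strand = logical(0), frequency = integer(0)))
  counted <- all[, list(frequency = .N), by = c("r1", "r2", "same_strand")]
  counted <- counted[counted$frequency >= params$min_frequency, ]
  data.table::setorderv(counted, c("r1", "r2", "same_strand"))
  as.data.frame(counted)
}
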