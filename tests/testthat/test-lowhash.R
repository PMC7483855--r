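test_that("feature extraction matches the worked example", {
  f <- extract_features(c(18L, 45L, 71L, 3L, 15L, 6L, 21L), 4)
  expect_equal(nrow(f), 4)
  expect_equal(f[1, ], c(18L, 45L, 71L, 3L))
  expect_equal(f[2, ], c(45L, 71L, 3L, 15L))
  expect_equal(f[3, ], c(71L, 3L, 15L, 6L))
  expect_equal(f[4, ], c(3L, 15L, 6L, 21L))

  expect_equal(nrow(extract_features(c(1L, 2L, 3L), 4)), 0)
  expect_equal(extract_features(c(5L, 9L, 2L), 1)[, 1], c(5L, 9L, 2L))
})

test_that("jaccard similarity handles containment and edge cases", {
  expect_equal(jaccard(1:5, 1:5), 1)
  expect_equal(jaccard(1:5, 6:10), 0)
  expect_equal(jaccard(integer(0), integer(0)), 0)
  # exact containment: |A|/|B|
  expect_equal(jaccard(1:50, 1:100), 0.5)
  a <- extract_features(c(1L, 2L, 3L, 4L, 5L), 2)
  expect_equal(jaccard(a, a), 1)
})

test_that("low-hash passes bucket deterministically and fractionally", {
  params <- lowhash_params(seed = 42)
  set.seed(1)
  ids <- lapply(1:40, function(i) sample.int(1000, 400, replace = TRUE))
  b1 <- lowhash_pass(ids, params, 0)
  b2 <- lowhash_pass(ids, params, 0)
  expect_identical(b1, b2)
  # different iterations use different hash functions
  b3 <- lowhash_pass(ids, params, 1)
  expect_false(identical(b1, b3))
  # identical marker sequences land in identical bucket sets
  ids2 <- c(ids, ids[1])
  b4 <- lowhash_pass(ids2, params, 0)
  expect_setequal(b4$bucket[b4$item == 41], b4$bucket[b4$item == 1])
  # expected low-hash features per read ~ hash_fraction * feature count
  nf <- sum(lengths(ids) - params$m + 1)
  hits <- nrow(b1)
  expect_lt(abs(hits - 0.01 * nf), 4 * sqrt(0.01 * nf))
})

test_that("overfull buckets are ignored for pair generation", {
  params <- lowhash_params(iterations = 1, max_bucket_size = 10,
                           min_frequency = 1, seed = 5)
  # 20 reads sharing one feature; every bucket from it has 20 occupants
  shared <- c(7L, 8L, 9L, 10L)
  ids <- lapply(1:20, function(i) shared)
  out <- find_candidate_pairs(ids, lapply(ids, rev), params)
  expect_equal(nrow(out), 0)
  # with 8 reads the bucket is small enough
  out2 <- find_candidate_pairs(ids[1:8], lapply(ids[1:8], rev),
                               lowhash_params(iterations = 40,
                                              hash_fraction = 0.5,
                                              min_frequency = 2, seed = 5))
  expect_gt(nrow(out2), 0)
  expect_true(all(out2$r1 < out2$r2))
})

test_that("candidate pairs find true overlaps and skip disjoint loci", {
  g <- simulate_genome(20000, seed = 15)
  sim <- simulate_reads(g, coverage = 8, seed = 16, length_meanlog = 8.5,
                        length_sdlog = 0.2)
  rl <- lapply(sim$reads, rle_encode)
  ms <- select_markers(10, 0.1, seed = 17)
  mf <- lapply(rl, find_markers, ms = ms)
  mr <- lapply(mf, marker_seq_revcomp, ms = ms)
  cand <- find_candidate_pairs(lapply(mf, `[[`, "ids"),
                               lapply(mr, `[[`, "ids"),
                               lowhash_params(seed = 18))
  expect_true(all(cand$frequency >= 2))
  lay <- sim$layout
  ov <- function(i, j) max(0, min(lay$end[i], lay$end[j]) -
                             max(lay$start[i], lay$start[j]) + 1)
  key <- paste(cand$r1, cand$r2)
  found <- outer(seq_len(nrow(lay)), seq_len(nrow(lay)), Vectorize(function(i, j)
    paste(min(i, j), max(i, j)) %in% key))
  hit <- 0L; tot <- 0L; false_big <- 0L
  for (i in seq_len(nrow(lay) - 1)) for (j in (i + 1):nrow(lay)) {
    o <- ov(i, j)
    if (o >= 5000) { tot <- tot + 1L; if (found[i, j]) hit <- hit + 1L }
    if (o == 0 && found[i, j]) false_big <- false_big + 1L
  }
  expect_gt(tot, 10)
  expect_gte(hit / tot, 0.95)        # recall on >=5 kb true overlaps
  expect_equal(false_big, 0)         # disjoint loci stay unpaired
  # pairs are reported canonically once
  expect_false(any(duplicated(data.frame(cand$r1, cand$r2, cand$same_strand))))
})
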