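test_that("frequent markers are excluded from alignment", {
  a <- c(rep(5L, 11), 1:20)
  b <- c(1:20, 5L)
  f <- filter_frequent_markers(a, b, 10)
  expect_false(any(a[f$a_keep] == 5L))
  expect_false(any(b[f$b_keep] == 5L))
  # all unique: untouched
  f2 <- filter_frequent_markers(1:10, 11:20, 10)
  expect_identical(f2$a_keep, 1:10)
  expect_identical(f2$b_keep, 1:10)
})

test_that("marker alignment reproduces simple chains", {
  p <- align_params(min_aligned_marker_count = 1)
  # identical sequences align fully with no skips
  al <- align_markers(1:50, 1:50, p)
  expect_equal(al$aligned_count, 50)
  expect_equal(al$total_skip, 0)
  expect_equal(al$trim_a, c(0L, 0L))
  expect_identical(al$pairs[, 1], al$pairs[, 2])

  # one substitution: skip of one on each read
  al2 <- align_markers(c(1L, 2L, 3L, 9L, 4L, 5L),
                       c(1L, 2L, 3L, 7L, 4L, 5L), p)
  expect_equal(al2$aligned_count, 5)
  expect_identical(al2$pairs[, 1], c(1L, 2L, 3L, 5L, 6L))
  expect_equal(al2$max_skip_seen, 1)

  # below the minimum aligned count -> rejection, not an error
  al3 <- align_markers(1:5, 1:5, align_params(min_aligned_marker_count = 40))
  expect_false(al3$accepted)
  expect_equal(al3$aligned_count, 5)
})

test_that("the skip bound excludes longer but invalid chains", {
  # an 8-marker insert in b (below the frequency filter threshold)
  a <- c(1:5, 100L, 6:10)
  b <- c(1:5, 91:98, 6:10)
  # unconstrained: all ten of 1:10 align (crossing skips 8 on b)
  loose <- align_markers(a, b, align_params(max_skip = 10, max_trim = 10,
                                            min_aligned_marker_count = 1))
  expect_equal(loose$aligned_count, 10)
  # with max_skip = 5 the crossing is forbidden: only one side aligns
  al <- align_markers(a, b, align_params(max_skip = 5, max_trim = 10,
                                         min_aligned_marker_count = 1))
  expect_equal(al$aligned_count, 5)
  expect_true(chain_is_valid(al$pairs, length(a), length(b), 5, 10))
})

test_that("constrained chain DP matches the exhaustive oracle", {
  set.seed(33)
  p <- align_params(max_skip = 4, max_trim = 3,
                    min_aligned_marker_count = 1)
  for (rep in 1:60) {
    na <- sample(5:20, 1); nb <- sample(5:20, 1)
    a <- sample.int(8, na, replace = TRUE)
    b <- sample.int(8, nb, replace = TRUE)
    orc <- oracle_chain(a, b, 4, 3)
    al <- align_markers(a, b, p)
    expect_equal(al$aligned_count, orc$count,
                 label = paste("count case", rep))
    if (orc$count > 0) {
      expect_equal(al$total_skip, orc$skip,
                   label = paste("skip case", rep))
      expect_true(chain_is_valid(al$pairs, na, nb, 4, 3))
      expect_true(all(a[al$pairs[, 1]] == b[al$pairs[, 2]]))
    }
  }
})

test_that("alignment is symmetric in its arguments", {
  set.seed(34)
  p <- align_params(max_skip = 5, max_trim = 5,
                    min_aligned_marker_count = 1)
  for (rep in 1:20) {
    a <- sample.int(10, 15, replace = TRUE)
    b <- sample.int(10, 15, replace = TRUE)
    ab <- align_markers(a, b, p)
    ba <- align_markers(b, a, p)
    expect_equal(ab$aligned_count, ba$aligned_count)
    expect_equal(ab$total_skip, ba$total_skip)
  }
})

test_that("strand symmetry: aligning the reverse complements mirrors", {
  ms <- select_markers(4, 0.5, seed = 21)
  set.seed(35)
  x <- rle_encode(rand_dna(800))
  y <- rle_encode(paste0(rand_dna(100), substr(rand_dna(3000), 1, 0),
                         rle_decode(x)))
  mx <- find_markers(x, ms); my <- find_markers(y, ms)
  p <- align_params(min_aligned_marker_count = 1)
  fwd <- align_markers(mx, my, p)
  rx <- marker_seq_revcomp(mx, ms); ry <- marker_seq_revcomp(my, ms)
  rev_al <- align_markers(rx, ry, p)
  expect_equal(rev_al$aligned_count, fwd$aligned_count)
  # the reversed chain maps ordinals o -> n + 1 - o
  expect_identical(rev_al$pairs[, 1],
                   rev(length(mx$ids) + 1L - fwd$pairs[, 1]))
  expect_identical(rev_al$pairs[, 2],
                   rev(length(my$ids) + 1L - fwd$pairs[, 2]))
})
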