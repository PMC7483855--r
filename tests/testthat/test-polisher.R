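hmm_default <- pairhmm_params()

test_that("full-band posteriors match an independent forward-backward", {
  set.seed(100)
  for (rep in 1:6) {
    m <- sample(10:40, 1); n <- sample(10:40, 1)
    r <- sample(0:3, m, replace = TRUE)
    s <- sample(0:3, n, replace = TRUE)
    guide <- cbind(c(1L, m), c(1L, n))
    hmm <- pairhmm_params(band = max(m, n) + 5L, threshold = 1e-4)
    got <- compute_alignment_posteriors(r, s, guide, hmm)
    orc <- r_forward_backward(r + 1L, s + 1L, hmm$trans, hmm$pm_eq, hmm$qins)
    expect_equal(got$loglik, orc$loglik, tolerance = 1e-9)
    for (t in seq_len(nrow(got$match))) {
      expect_equal(got$match$p[t],
                   orc$match[got$match$i[t], got$match$j[t]],
                   tolerance = 1e-6)
    }
    for (t in seq_len(nrow(got$ins))) {
      expect_equal(got$ins$p[t],
                   orc$ins[got$ins$i[t], got$ins$j[t] + 1L],
                   tolerance = 1e-6)
    }
    # every sufficiently large oracle posterior is reported
    big <- which(orc$match >= 2e-4, arr.ind = TRUE)
    expect_true(all(paste(big[, 1], big[, 2]) %in%
                      paste(got$match$i, got$match$j)))
  }
})

test_that("a read identical to the assembly aligns on the diagonal", {
  set.seed(101)
  r <- sample(0:3, 30, replace = TRUE)
  ap <- compute_alignment_posteriors(r, r, cbind(c(1L, 30L), c(1L, 30L)),
                                     hmm_default)
  diag_p <- ap$match$p[ap$match$i == ap$match$j]
  expect_equal(length(diag_p), 30)
  expect_true(all(diag_p > 0.99))
})

test_that("degenerate bands do not crash and are reported", {
  # a guide mapping the read far off the diagonal with a tiny band:
  # either the banded recursion still finds some (very unlikely) path,
  # or the read is skipped with a warning and NULL
  out <- withCallingHandlers(
    compute_alignment_posteriors(c(0L, 1L, 2L, 3L, 0L, 1L),
                                 c(3L, 2L, 1L, 0L, 3L, 2L),
                                 cbind(c(1L, 6L), c(100L, 200L)),
                                 pairhmm_params(band = 2L)),
    warning = function(w) invokeRestart("muffleWarning"))
  expect_true(is.null(out) || is.finite(out$loglik))
})

test_that("multi-base indel expansion applies the minimum rule", {
  ap <- list(match = data.frame(i = integer(0), j = integer(0),
                                p = numeric(0)),
             ins = data.frame(i = c(4L, 5L), j = c(7L, 7L), p = c(0.8, 0.6)),
             del = data.frame(i = c(2L, 2L, 2L), j = c(3L, 4L, 5L),
                              p = c(0.5, 0.4, 0.45)))
  ex <- expand_multibase_indels(ap)
  expect_equal(nrow(ex$ins_multi), 1)
  expect_equal(ex$ins_multi$p, 0.6)
  expect_equal(ex$ins_multi[, c("i1", "i2", "j")],
               data.frame(i1 = 4L, i2 = 5L, j = 7L))
  # deletions: all contiguous subranges of the run
  expect_equal(nrow(ex$del_multi), 3)
  expect_equal(ex$del_multi$p[ex$del_multi$j1 == 3 & ex$del_multi$j2 == 5],
               0.4)
  # single entries spawn nothing
  ap2 <- list(match = ap$match,
              ins = data.frame(i = 4L, j = 7L, p = 0.8),
              del = ap$del[0, ])
  expect_equal(nrow(expand_multibase_indels(ap2)$ins_multi), 0)
})

test_that("the min-rule is an upper bound on the exact joint probability", {
  # exhaustive path enumeration on a tiny instance: probability that both
  # read bases 2 and 3 are inserted after assembly position 2
  r <- c(0L, 2L, 3L, 1L)
  s <- c(0L, 2L, 1L)
  hmm <- hmm_default
  lt <- log(hmm$trans)
  paths <- list()
  walk <- function(i, j, st, lp, ops) {
    if (i == length(r) && j == length(s)) {
      paths[[length(paths) + 1L]] <<- list(lp = lp, ops = ops)
      return()
    }
    if (i < length(r) && j < length(s)) {
      em <- if (r[i + 1] == s[j + 1]) log(hmm$pm_eq) else log((1 - hmm$pm_eq) / 3)
      walk(i + 1, j + 1, 1L, lp + lt[st, 1] + em, c(ops, sprintf("M%d.%d", i + 1, j + 1)))
    }
    if (i < length(r))
      walk(i + 1, j, 2L, lp + lt[st, 2] + log(hmm$qins),
           c(ops, sprintf("I%d.%d", i + 1, j)))
    if (j < length(s))
      walk(i, j + 1, 3L, lp + lt[st, 3], c(ops, sprintf("D%d.%d", i, j + 1)))
  }
  walk(0L, 0L, 1L, 0, character(0))
  lps <- vapply(paths, `[[`, numeric(1), "lp")
  total <- max(lps) + log(sum(exp(lps - max(lps))))
  joint <- vapply(paths, function(p)
    all(c("I2.2", "I3.2") %in% p$ops), logical(1))
  exact <- exp(max(lps[joint]) + log(sum(exp(lps[joint] - max(lps[joint])))) -
                 total)
  ap <- compute_alignment_posteriors(r, s, cbind(c(1L, 4L), c(1L, 3L)),
                                     pairhmm_params(band = 10L,
                                                    threshold = 1e-6))
  ex <- expand_multibase_indels(ap)
  est <- ex$ins_multi$p[ex$ins_multi$i1 == 2 & ex$ins_multi$i2 == 3 &
                          ex$ins_multi$j == 2]
  expect_equal(length(est), 1L)
  expect_gte(est + 1e-9, exact)
})

test_that("POA weights have their probabilistic interpretation", {
  set.seed(102)
  s <- sample(0:3, 60, replace = TRUE)
  guide <- cbind(c(1L, 60L), c(1L, 60L))
  posts <- lapply(1:10, function(i) {
    expand_multibase_indels(
      compute_alignment_posteriors(s, s, guide, hmm_default))
  })
  poa <- build_weighted_poa(s, posts, rep(list(s), 10))
  own <- poa$w[cbind(s + 1L, seq_along(s))]
  expect_true(all(own > 9.5))
  expect_true(all(poa$w[cbind(((s + 1L) %% 4L) + 1L, seq_along(s))] < 0.2))
  expect_lt(sum(poa$dels$weight), 0.5)
  expect_lt(sum(poa$ins$weight), 0.5)
  expect_equal(mean(poa$cov), 10, tolerance = 0.05)

  # one read with a real deletion contributes ~its posterior as a
  # deletion edge; weights are fractional
  rdel <- s[-30]
  pdel <- expand_multibase_indels(
    compute_alignment_posteriors(rdel, s, cbind(c(1L, 59L), c(1L, 60L)),
                                 hmm_default))
  poa2 <- build_weighted_poa(s, list(pdel), list(rdel))
  hit <- poa2$dels[poa2$dels$j1 <= 30 & poa2$dels$j2 >= 29, ]
  expect_gt(sum(hit$weight), 0.5)
  expect_true(any(abs(poa2$w - round(poa2$w)) > 1e-6))
})

test_that("a planted substitution is corrected by edit evaluation", {
  set.seed(103)
  truth <- sample(0:3, 200, replace = TRUE)
  truth <- truth[c(TRUE, diff(truth) != 0)]   # RLE-valid
  n <- length(truth)
  draft <- truth
  draft[100] <- (draft[100] + 2L) %% 4L
  guide <- cbind(c(1L, n), c(1L, n))
  reads <- rep(list(truth), 20)
  res <- nanoasm:::polish_chunk(draft, reads, rep(list(guide), 20),
                                hmm_default, polish_params())
  expect_identical(res$asm, truth)

  # clean draft with clean reads: returned unchanged
  res0 <- nanoasm:::polish_chunk(truth, reads, rep(list(guide), 20),
                                 hmm_default, polish_params())
  expect_identical(res0$asm, truth)
})

test_that("run-length model training and decoding behave", {
  # error-free observations give identity matrices
  p0 <- data.frame(base = "A", true = rep(1:10, each = 20),
                   obs = rep(1:10, each = 20))
  m0 <- train_runlength_model(p0)
  expect_equal(m0$mats$A[1:10, 1:10], diag(10))
  expect_true(all(rowSums(m0$mats$A[1:10, ]) == 1))
  expect_false(any(m0$observed$C))

  # clamping out-of-range observations warns
  expect_warning(train_runlength_model(
    data.frame(base = "A", true = 60, obs = 3)), "clamped")

  # identity model decodes repeated observations directly
  ident <- new_runlength_model(list(A = diag(50), C = diag(50),
                                    G = diag(50), T = diag(50)))
  expect_equal(decode_run_lengths(ident, c(5L, 5L, 5L), "A"), 5L)

  # the printed toy: P(4|5)=0.6, P(5|5)=0.4, P(4|4)=0.9, P(5|4)=0.1
  mA <- matrix(0, 50, 50)
  mA[4, 4] <- 0.9; mA[4, 5] <- 0.1
  mA[5, 4] <- 0.6; mA[5, 5] <- 0.4
  toy <- new_runlength_model(list(A = mA, C = mA, G = mA, T = mA))
  obs <- c(4L, 4L, 5L)
  # brute-force argmax over candidate lengths
  ll <- vapply(c(4, 5), function(y) sum(log(mA[y, obs])), numeric(1))
  expect_equal(c(4, 5)[which.max(ll)], 5)
  expect_equal(decode_run_lengths(toy, obs, "A"), 5L)

  # model files round-trip
  path <- tempfile(fileext = ".csv")
  gen <- runlength_error_model()
  write_runlength_model(gen, path)
  back <- read_runlength_model(path)
  expect_equal(back$mats$A, gen$mats$A, tolerance = 1e-12)
  unlink(path)
})

test_that("Bayesian decoding beats plurality on long homopolymers", {
  gen <- runlength_error_model()
  set.seed(104)
  pairs <- do.call(rbind, lapply(1:12, function(y) {
    data.frame(base = "A", true = y,
               obs = sample.int(50, 3000, replace = TRUE,
                                prob = gen$mats$A[y, ]))
  }))
  fit <- train_runlength_model(pairs)
  correct_bayes <- 0L; correct_plur <- 0L; trials <- 0L
  for (y in 6:10) {
    for (rep in 1:60) {
      obs <- sample.int(50, 30, replace = TRUE, prob = gen$mats$A[y, ])
      trials <- trials + 1L
      if (suppressWarnings(decode_run_lengths(fit, obs, "A")) == y)
        correct_bayes <- correct_bayes + 1L
      if (plurality_repeat_count(obs) == y)
        correct_plur <- correct_plur + 1L
    }
  }
  expect_gt(correct_bayes, correct_plur)
})

test_that("chunk downsampling and stitching contracts hold", {
  # discard probability is non-positive when coverage fits max_depth
  pp <- polish_params()
  n_c <- (pp$chunk_size + 2 * pp$chunk_boundary) * pp$max_depth
  expect_gte((pp$chunk_size + 2 * pp$chunk_boundary) * pp$max_depth / n_c, 1)

  # identical overlap: stitch is exact concatenation minus the overlap
  set.seed(105)
  whole <- sample(0:3, 300, replace = TRUE)
  whole <- whole[c(TRUE, diff(whole) != 0)]
  counts <- sample.int(3, length(whole), replace = TRUE)
  left <- list(bases = whole[1:150], counts = counts[1:150])
  right <- list(bases = whole[101:length(whole)],
                counts = counts[101:length(whole)])
  st <- nanoasm:::stitch_rle(left, right, 50L)
  expect_identical(st$bases, whole)
  expect_identical(st$counts, counts)
})

test_that("end-to-end polishing improves a planted-error draft", {
  g <- simulate_genome(6000, seed = 106)
  sim <- simulate_reads(g, coverage = 25, seed = 107,
                        length_meanlog = 7.8, length_sdlog = 0.2)
  model <- train_runlength_model(make_runlength_training_pairs(sim))
  set.seed(108)
  chars <- strsplit(g, "")[[1]]
  sp <- sample(200:5800, 15)
  chars[sp] <- c("A", "C", "G", "T")[
    (nanoasm:::dna_to_int(paste0(chars[sp], collapse = "")) +
       sample(1:3, 15, TRUE)) %% 4 + 1]
  dp <- sample(200:5800, 4)
  pieces <- chars; pieces[dp] <- ""
  draft <- paste0(pieces, collapse = "")
  d0 <- nanoasm:::.banded_fit_distance(draft, g, 200)
  pol <- suppressWarnings(polish_assembly(draft, sim$reads, model = model,
                                          seed = 109))
  d1 <- nanoasm:::.banded_fit_distance(pol$polished, g, 200)
  expect_lt(d1, d0)
})
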