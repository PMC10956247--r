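# motif extraction: MI scoring, seed expansion, the background merge test,
# interval merging, and PWM assembly

test_that("cosine mutual information behaves like a cosine", {
  v <- matrix(c(1, 2, 3, 0, 0, 0), nrow = 2, byrow = TRUE)
  w <- matrix(c(2, 4, 6, 3, -3, 0), nrow = 2, byrow = TRUE)
  mi <- mutual_information(v, w, method = "cosine")
  expect_equal(mi[1, 1], 1)                 # scale invariance
  expect_equal(mi[2, 1], 0)                 # zero vector convention
  u <- matrix(c(1, 0, 0, 1), nrow = 2, byrow = TRUE)
  expect_equal(mutual_information(u, u)[1, 2], 0)  # orthogonal
  expect_equal(mutual_information(u, u)[1, 1], 1)  # identical
  dot <- mutual_information(v, w, method = "dot")
  expect_equal(dot[1, 1], sum(v[1, ] * w[1, ]))
  expect_error(mutual_information(v, w[, 1:2]), "dsq")
})

test_that("denoising subtracts the negative-set grand mean", {
  mi0 <- matrix(c(0, 0.2, 0.4, 0.6), 2, 2)
  mi1 <- matrix(0.3, 2, 2)
  dn <- denoise_mi(mi1, mi0)
  expect_equal(attr(dn, "noise"), 0.3)
  expect_equal(unclass(dn)[1, 1], 0)
  # constant negatives shift by exactly that constant
  dn2 <- denoise_mi(mi1, matrix(0.1, 3, 3))
  expect_equal(as.numeric(dn2), rep(0.2, 4))
  expect_error(denoise_mi(mi1, matrix(numeric(0), 0, 0)), "empty")
})

test_that("seed expansion applies the center arithmetic and bounds rule", {
  occ <- tibble::tibble(seq = 1L, start = c(10L, 1L, 50L))
  out <- quiet(expand_seed(occ, lenk = 5, seq_len = 101))
  # strk = 10 -> ck = 12, kl = [8,12], kr = [13,17], candidate [8,17]
  expect_equal(out$ck[1], 12)
  expect_equal(out$kl_start[1], 8)
  expect_equal(out$kr_end[1], 17)
  # strk = 1 -> kl starts at -1: skipped
  expect_false(1L %in% out$start)
  # candidate width is always 2 * lenk before merging
  expect_equal(unique(out$kr_end - out$kl_start + 1), 10)
  expect_message(expand_seed(occ, 5, 101), "skipped 1")
})

test_that("the background co-occurrence test compares signed PMI weights", {
  # positives: n=4, kl/kr co-occur in both their sequences
  pos <- tibble::tibble(id = paste0("p", 1:4),
                        seq = c("AAATTT", "AAATTT", "CCCGGG", "CCCGGG"))
  # negatives: kl/kr co-occur in one sequence only
  neg <- tibble::tibble(id = paste0("n", 1:4),
                        seq = c("AAATTT", "AAACCC", "TTTCCC", "GGGCCC"))
  pv <- kmer_vocabulary(pos, 3)
  nv <- kmer_vocabulary(neg, 3)
  # wco = -ln((2/4)/(2/4 * 2/4)) = -ln 2 ; bwco = -ln((1/4)/(2/4*2/4)) = 0
  expect_true(coexist_test("AAA", "TTT", pv, nv))
  # pair absent from positives: rejected regardless of background
  expect_false(coexist_test("GGG", "TTT", pv, nv))
  # pair co-occurring in positives but never in negatives: +Inf background
  expect_true(coexist_test("CCC", "CGG", pv, nv))
  # vectorized over pairs
  expect_equal(coexist_test(c("AAA", "GGG"), c("TTT", "TTT"), pv, nv),
               c(TRUE, FALSE))
})

test_that("overlap merging unions transitively but spares adjacency", {
  iv <- tibble::tibble(seq = c(1, 1, 2, 2, 3, 3, 3),
                       start = c(8, 15, 8, 18, 1, 5, 11),
                       end = c(17, 24, 17, 25, 10, 12, 20))
  out <- merge_overlaps(iv)
  expect_equal(out[out$seq == 1, ]$start, 8)
  expect_equal(out[out$seq == 1, ]$end, 24)
  # [8,17] and [18,25] touch but do not share a position
  expect_equal(nrow(out[out$seq == 2, ]), 2)
  # chain [1,10] + [5,12] + [11,20] collapses to [1,20]
  expect_equal(out[out$seq == 3, ]$start, 1)
  expect_equal(out[out$seq == 3, ]$end, 20)
  empty <- merge_overlaps(tibble::tibble(seq = integer(), start = integer(),
                                         end = integer()))
  expect_equal(nrow(empty), 0)
})

test_that("PWM assembly honors pseudocounts, support, and alignment", {
  # 10 identical 10-mers: one motif, consensus columns at (10 + pc)/(10 + 4pc)
  tfbs <- tibble::tibble(subseq = rep("ACGTACGTAC", 10))
  mots <- build_motifs(tfbs, min_sites = 5, pseudocount = 0.25)
  expect_length(mots, 1)
  expect_equal(mots[[1]]$nsites, 10)
  expect_equal(unname(apply(mots[[1]]$pwm, 2, max)), rep(10.25 / 11, 10))
  expect_equal(unname(colSums(mots[[1]]$pwm)), rep(1, 10))

  # two dissimilar groups form two motifs
  two <- tibble::tibble(subseq = c(rep("ACGTACGTAC", 6),
                                   rep("TTGCATTGCATTGCA", 6)))
  expect_length(build_motifs(two), 2)

  # support below min_sites is discarded
  few <- tibble::tibble(subseq = rep("ACGTACGTAC", 4))
  expect_length(build_motifs(few, min_sites = 5), 0)

  # register-shifted copies of one site align into a single motif
  core <- "ACGTACGTAC"
  shifted <- c(paste0("TT", core), paste0(core, "GG"), paste0("A", core, "C"),
               rep(core, 4))
  mots <- build_motifs(tibble::tibble(subseq = shifted), min_sites = 5)
  expect_length(mots, 1)
  expect_gte(mots[[1]]$nsites, 5)
  expect_true(grepl(core, mots[[1]]$consensus) ||
                grepl(mots[[1]]$consensus, core))
})

test_that("interval recall counts overlapped ground-truth instances", {
  truth <- tibble::tibble(id = c("a", "a", "b"), start = c(10, 40, 5),
                          end = c(17, 47, 12))
  tfbs <- tibble::tibble(id = c("a", "b"), start = c(15, 50), end = c(20, 60))
  expect_equal(interval_recall(truth, tfbs), 1 / 3)
  expect_equal(interval_recall(truth, truth), 1)
})

test_that("the full extraction pipeline recovers a strongly planted motif", {
  run <- planted_run(1)
  ms <- run$motifs
  expect_s3_class(tidy(ms), "tbl_df")
  expect_gt(length(ms$motifs), 0)
  # every reported interval lies inside its sequence
  expect_true(all(ms$tfbs$start >= 1 & ms$tfbs$end <= 101))
  # all PWMs are column-stochastic
  for (mo in ms$motifs) {
    expect_equal(unname(colSums(mo$pwm)), rep(1, mo$length), tolerance = 1e-9)
  }
  # the planted PWM is among the reported motifs
  best <- max(vapply(ms$motifs,
                     function(mo) pwm_similarity(mo$pwm, run$pwm)$r,
                     numeric(1)))
  expect_gt(best, 0.8)
})
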