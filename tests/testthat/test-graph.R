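# multi-view graph construction: hand-checked weights and brute-force parity

# a corpus engineered so occurrence counts are easy to reason about:
# k-mer sets per sequence are controlled via shared prefixes
hand_vocab <- function(seqs, lenk = 3) {
  kmer_vocabulary(tibble::tibble(id = paste0("s", seq_along(seqs)),
                                 seq = seqs), lenk)
}

test_that("co-occurrence weights follow the negated-PMI form", {
  # 4 sequences; "AAA" in 1,2; "CCC" in 3,4; "GGG" in 2,3
  vocab <- hand_vocab(c("AAAT", "AAAGGG", "GGGCCC", "CCCT"))
  W <- coexisting_weights(vocab)
  k <- function(x) match(x, vocab$kmers)
  # nums("AAA","CCC") = 0: no edge
  expect_equal(W[k("AAA"), k("CCC")], 0)
  # num(AAA)=2, num(GGG)=2, nums=1, n=4 -> Q = P*P -> weight 0 (independence)
  expect_equal(W[k("AAA"), k("GGG")], 0)
  # num(AAA)=2, num(AAT)=1, nums=1 -> -ln((1/4)/(2/4 * 1/4)) = -ln 2
  expect_equal(W[k("AAA"), k("AAT")], -log(2))
  expect_equal(diag(W), rep(0, vocab$m))
  expect_equal(max(abs(W - t(W))), 0)
})

test_that("similarity weights are Hamming distances", {
  vocab <- hand_vocab(c("ACGTA", "ACGTT", "TTTTT"), lenk = 5)
  W <- similarity_weights(vocab)
  k <- function(x) match(x, vocab$kmers)
  expect_equal(W[k("ACGTA"), k("ACGTA")], 0)
  expect_equal(W[k("ACGTA"), k("ACGTT")], 1)
  expect_equal(W[k("ACGTA"), k("TTTTT")], 4)
  expect_true(all(W >= 0 & W <= 5))
  # off-diagonal zeros impossible: distinct k-mers differ somewhere
  expect_true(all(W[upper.tri(W)] > 0))
})

test_that("jaccard weights are intersection over union of occurrence sets", {
  # AAA occurs in seqs 1,2,3; TTT in 2,3,4 -> 2/4
  vocab <- hand_vocab(c("AAAC", "AAATTT", "TTTAAA", "TTTC"))
  W <- jaccard_weights(vocab)
  k <- function(x) match(x, vocab$kmers)
  expect_equal(W[k("AAA"), k("TTT")], 0.5)
  expect_equal(diag(W), rep(1, vocab$m))
  expect_equal(W[k("AAC"), k("TTC")], 0) # disjoint occurrence sets
  expect_true(all(W >= 0 & W <= 1))
})

test_that("inclusive weights are tf-idf with natural log", {
  # n = 4; "AAA" occurs twice in seq 1 only -> 2 * ln 4
  vocab <- hand_vocab(c("AAAA", "CCCC", "CCCG", "GCCC"))
  W <- as.matrix(inclusive_weights(vocab))
  k <- function(x) match(x, vocab$kmers)
  expect_equal(W[k("AAA"), 1], 2 * log(4))
  expect_equal(W[k("AAA"), 2], 0) # absent -> no edge
  # a k-mer in all n sequences has zero idf everywhere
  all4 <- hand_vocab(c("CCCA", "CCCT", "CCCG", "ACCC"))
  Wa <- as.matrix(inclusive_weights(all4))
  expect_equal(unname(Wa[match("CCC", all4$kmers), ]), rep(0, 4))
})

test_that("row normalization uses absolute sums and spares zero rows", {
  m <- rbind(c(2, 2), c(-1, 1), c(0, 0))
  out <- row_normalize(m)
  expect_equal(out[1, ], c(0.5, 0.5))
  expect_equal(out[2, ], c(-0.5, 0.5))
  expect_equal(sum(abs(out[2, ])), 1)
  expect_equal(out[3, ], c(0, 0))
  # literal signed-sum mode
  expect_equal(row_normalize(rbind(c(3, 1)), "signed")[1, ], c(0.75, 0.25))
})

test_that("build_graph matches the brute-force oracle across random corpora", {
  for (seed in 1:20) {
    n <- sample(4:12, 1)
    len <- sample(8:30, 1)
    corpus <- random_corpus(n, len, seed = seed * 101)
    g <- build_graph(corpus, lenk = 3)
    o <- oracle_graph(corpus$seq, 3)
    expect_equal(g$vocab$kmers, o$kmers)
    expect_lt(max(abs(g$Wco - o$Wco)), 1e-10)
    expect_lt(max(abs(g$Wsim - o$Wsim)), 1e-10)
    expect_lt(max(abs(g$Wjac - o$Wjac)), 1e-10)
    expect_lt(max(abs(as.matrix(g$Winclu) - o$Winclu)), 1e-10)
  }
})

test_that("graph views respect their structural invariants", {
  corpus <- random_corpus(12, 40, seed = 31)
  g <- build_graph(corpus, lenk = 5)
  expect_equal(max(abs(g$Wco - t(g$Wco))), 0)
  expect_equal(max(abs(g$Wsim - t(g$Wsim))), 0)
  expect_equal(max(abs(g$Wjac - t(g$Wjac))), 0)
  expect_true(all(g$Wjac >= 0 & g$Wjac <= 1))
  expect_true(all(g$Wsim %in% 0:5))
  expect_true(all(as.matrix(g$Winclu) >= 0))
  rs <- rowSums(abs(g$Ect))
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-9))
})

test_that("sequence order permutes Winclu columns and nothing else", {
  corpus <- random_corpus(8, 20, seed = 77)
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  g1 <- build_graph(corpus, lenk = 3)
  g2 <- build_graph(corpus[perm, ], lenk = 3)
  expect_equal(g1$Wco, g2$Wco)
  expect_equal(g1$Wsim, g2$Wsim)
  expect_equal(g1$Wjac, g2$Wjac)
  expect_equal(as.matrix(g1$Winclu)[, perm], as.matrix(g2$Winclu))
})

test_that("duplicating every sequence leaves the set-ratio views unchanged", {
  corpus <- random_corpus(6, 18, seed = 5)
  doubled <- dplyr::bind_rows(corpus,
                              dplyr::mutate(corpus, id = paste0(id, "_b")))
  g1 <- build_graph(corpus, lenk = 3)
  g2 <- build_graph(doubled, lenk = 3)
  expect_equal(g1$Wsim, g2$Wsim)
  expect_equal(g1$Wjac, g2$Wjac)
})

test_that("a single-sequence corpus degenerates as expected", {
  g <- build_graph(tibble::tibble(id = "s", seq = "ACGTACGTAA"), lenk = 3)
  expect_equal(ncol(g$Winclu), 1)
  expect_true(all(g$Wjac == 1))
})

test_that("graph export writes readable Matrix Market views", {
  dir <- withr::local_tempdir()
  g <- build_graph(random_corpus(4, 12, seed = 8), lenk = 3)
  export_graph(g, dir)
  back <- Matrix::readMM(file.path(dir, "Wjac.mtx"))
  expect_equal(as.matrix(back), g$Wjac, ignore_attr = TRUE)
  nodes <- readr::read_tsv(file.path(dir, "kmer_nodes.tsv"),
                           show_col_types = FALSE)
  expect_equal(nodes$kmer, g$vocab$kmers)
})
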