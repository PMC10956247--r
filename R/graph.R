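# the four-view heterogeneous graph: edge-weight matrices over k-mer and
# sequence nodes, plus the row-normalized initial embeddings

#' Co-occurrence edge weights between k-mers
#'
#' For k-mers p and j with joint sequence frequency `nums(p, j) > 0`, the
#' weight is `-log(Q / (P(p) * P(j)))` with `P = num / n` and `Q = nums / n`
#' (natural log): the negated pointwise mutual information of the pair across
#' sequences. Pairs that never co-occur, and the diagonal, carry no edge (0).
#' Note the sign: strongly associated pairs get *negative* weights, which is
#' what the motif-merge test (`wco < bwco`) relies on.
#'
#' @param vocab A [kmer_vocabulary()].
#' @return Dense m x m symmetric matrix.
#' @export
coexisting_weights <- function(vocab) {
  n <- vocab$n
  nums <- as.matrix(Matrix::tcrossprod(vocab$occ))
  P <- vocab$num / n
  W <- matrix(0, vocab$m, vocab$m)
  nz <- nums > 0
  PP <- outer(P, P)
  W[nz] <- -log((nums[nz] / n) / PP[nz])
  diag(W) <- 0
  W
}

#' Hamming-distance edge weights between k-mers
#'
#' Entry (p, j) counts the mismatching positions between the two k-mer
#' strings; the diagonal is 0. Weights are the raw distance (dissimilar pairs
#' weigh more), as defined; `build_graph(sim_transform = "reverse")` flips
#' this to `lenk - Hamming` for propagation experiments.
#'
#' @param vocab A [kmer_vocabulary()].
#' @return Dense m x m symmetric integer matrix with values in `0:lenk`.
#' @export
similarity_weights <- function(vocab) {
  cm <- matrix(unlist(strsplit(vocab$kmers, ""), use.names = FALSE),
               nrow = vocab$m, byrow = TRUE)
  D <- matrix(0L, vocab$m, vocab$m)
  for (pos in seq_len(vocab$lenk)) {
    D <- D + outer(cm[, pos], cm[, pos], "!=")
  }
  D
}

#' Jaccard edge weights between k-mers
#'
#' Entry (p, j) is the Jaccard index of the two k-mers' sequence-occurrence
#' sets, `|Sk(p) ∩ Sk(j)| / |Sk(p) ∪ Sk(j)|`; the diagonal is 1.
#'
#' @param vocab A [kmer_vocabulary()].
#' @return Dense m x m symmetric matrix with values in `[0, 1]`.
#' @export
jaccard_weights <- function(vocab) {
  nums <- as.matrix(Matrix::tcrossprod(vocab$occ))
  uni <- outer(vocab$num, vocab$num, "+") - nums
  J <- nums / uni
  J[uni == 0] <- 0
  J
}

#' TF-IDF inclusive edge weights between k-mers and sequences
#'
#' Entry (p, i) is `tf(k(p), s(i)) * log(n / num(k(p)))` (natural log) when
#' k-mer p occurs in sequence i, else 0: term frequency scaled by inverse
#' document frequency, linking each sequence node to its constituent k-mers.
#'
#' @param vocab A [kmer_vocabulary()].
#' @return Sparse m x n non-negative matrix.
#' @export
inclusive_weights <- function(vocab) {
  idf <- log(vocab$n / vocab$num)
  Matrix::Diagonal(x = idf) %*% vocab$tf
}

#' L1 row normalization
#'
#' Divides every row by the sum of absolute values of its entries (so signed
#' rows keep their sign pattern but get unit L1 norm); all-zero rows are left
#' unchanged. `mode = "signed"` divides by the plain row sum instead — the
#' literal normalization formula — which is ill-conditioned when a signed row
#' nearly cancels, hence not the default.
#'
#' @param mat A numeric matrix.
#' @param mode `"l1"` (default) or `"signed"`.
#' @return The row-normalized matrix.
#' @export
row_normalize <- function(mat, mode = c("l1", "signed")) {
  mode <- match.arg(mode)
  s <- if (mode == "l1") rowSums(abs(mat)) else rowSums(mat)
  keep <- s != 0
  mat[keep, ] <- mat[keep, , drop = FALSE] / s[keep]
  mat
}

#' Build the full multi-view heterogeneous graph of a corpus
#'
#' Computes the four edge-weight matrices (co-occurrence, Hamming similarity,
#' Jaccard, TF-IDF inclusion) over the corpus vocabulary, plus the
#' row-normalized initial k-mer embeddings used by the network's first layer.
#'
#' @param corpus A prepared corpus tibble ([prepare_corpus()]), or any tibble
#'   with `id` and `seq`.
#' @param lenk k-mer width (default 5).
#' @param sim_transform `"hamming"` (raw distance, the definition) or
#'   `"reverse"` (`lenk - Hamming`, so similar k-mers weigh more).
#' @param normalize Row normalization mode for the initial embeddings, see
#'   [row_normalize()].
#' @return An object of class `"multiview_graph"`: list with `vocab`, the
#'   weight matrices `Wco`, `Wsim`, `Wjac`, `Winclu`, the initial embeddings
#'   `Ect`, `Est`, `Ejt`, and `m`, `n`, `lenk`, `seq_ids`.
#' @examples
#' g <- build_graph(tibble::tibble(id = c("a", "b"),
#'                                 seq = c("ACGTAC", "ACGTTT")), lenk = 3)
#' g$m
#' @export
build_graph <- function(corpus, lenk = 5,
                        sim_transform = c("hamming", "reverse"),
                        normalize = c("l1", "signed")) {
  sim_transform <- match.arg(sim_transform)
  normalize <- match.arg(normalize)
  if (lenk > 8) abort("lenk > 8 is unsupported: the dense m x m views grow as 4^(2*lenk)")
  vocab <- kmer_vocabulary(corpus, lenk)
  Wco <- coexisting_weights(vocab)
  Wsim <- similarity_weights(vocab)
  if (sim_transform == "reverse") Wsim <- lenk - Wsim
  Wjac <- jaccard_weights(vocab)
  Winclu <- inclusive_weights(vocab)
  structure(
    list(vocab = vocab, Wco = Wco, Wsim = Wsim, Wjac = Wjac, Winclu = Winclu,
         Ect = row_normalize(Wco, normalize),
         Est = row_normalize(Wsim, normalize),
         Ejt = row_normalize(Wjac, normalize),
         m = vocab$m, n = vocab$n, lenk = lenk, seq_ids = vocab$seq_ids),
    class = "multiview_graph"
  )
}

#' @export
print.multiview_graph <- function(x, ...) {
  cat(sprintf(
    "<multiview_graph> %d k-mer nodes (lenk = %d), %d sequence nodes, 4 views\n",
    x$m, x$lenk, x$n))
  invisible(x)
}

#' Export the graph views as Matrix Market files
#'
#' Writes each view (`Wco`, `Wsim`, `Wjac`, `Winclu`) as a `.mtx` file plus
#' TSVs mapping row/column indices to k-mers and sequence ids, for external
#' inspection.
#'
#' @param graph A [build_graph()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
export_graph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  views <- list(Wco = graph$Wco, Wsim = graph$Wsim, Wjac = graph$Wjac,
                Winclu = graph$Winclu)
  for (nm in names(views)) {
    Matrix::writeMM(methods::as(methods::as(views[[nm]], "generalMatrix"),
                                "CsparseMatrix"),
                    file.path(dir, paste0(nm, ".mtx")))
  }
  readr::write_tsv(tibble(index = seq_len(graph$m), kmer = graph$vocab$kmers),
                   file.path(dir, "kmer_nodes.tsv"))
  readr::write_tsv(tibble(index = seq_len(graph$n), id = graph$seq_ids),
                   file.path(dir, "sequence_nodes.tsv"))
  invisible(dir)
}
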