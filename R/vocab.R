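# k-mer vocabulary: the ordered set of unique k-mers across a corpus together
# with the occurrence statistics every edge weight is computed from

#' Build the k-mer vocabulary of a corpus
#'
#' Indexes every unique k-mer across all sequences (step-1 windows) and
#' records, per k-mer: which sequences contain it (the occurrence set
#' `Sk`), how many sequences that is (`num`), its per-sequence term frequency
#' (`tf`), and every 1-based start position.
#'
#' @param corpus Tibble with `id` and `seq` columns (any extra columns such
#'   as `label` and `split` are carried along untouched by downstream users).
#' @param lenk k-mer width (default 5).
#' @return An object of class `"kmer_vocab"`: a list with
#'   * `lenk`, `kmers` (sorted unique k-mer strings), `m`, `n`, `seq_ids`;
#'   * `tf`: m x n sparse count matrix (k-mer by sequence);
#'   * `occ`: m x n sparse 0/1 occurrence matrix;
#'   * `num`: per-k-mer sequence counts (`rowSums(occ)`);
#'   * `positions`: tibble (`seq`, `kmer`, `start`) of every occurrence,
#'     indices into `seq_ids` / `kmers`.
#' @examples
#' vocab <- kmer_vocabulary(tibble::tibble(id = "s1", seq = "AAAAAA"), lenk = 5)
#' vocab$kmers
#' @export
kmer_vocabulary <- function(corpus, lenk = 5) {
  stopifnot(all(c("id", "seq") %in% names(corpus)))
  if (nrow(corpus) == 0) abort("cannot build a vocabulary from an empty corpus")
  if (!is_count(lenk) || lenk < 1) abort("`lenk` must be a positive integer")
  seqs <- corpus$seq
  n <- length(seqs)
  per_seq <- purrr::map(seqs, function(s) {
    L <- nchar(s)
    if (L < lenk) return(character(0))
    starts <- seq_len(L - lenk + 1)
    substring(s, starts, starts + lenk - 1)
  })
  lens <- lengths(per_seq)
  if (all(lens == 0)) abort("every sequence is shorter than `lenk`")
  kmers <- sort(unique(unlist(per_seq, use.names = FALSE)))
  m <- length(kmers)
  positions <- tibble(
    seq = rep.int(seq_len(n), lens),
    kmer = match(unlist(per_seq, use.names = FALSE), kmers),
    start = unlist(purrr::map(lens, seq_len), use.names = FALSE)
  )
  tf <- Matrix::sparseMatrix(i = positions$kmer, j = positions$seq, x = 1,
                             dims = c(m, n))
  occ <- tf
  occ@x <- rep(1, length(occ@x))
  structure(
    list(lenk = lenk, kmers = kmers, m = m, n = n, seq_ids = corpus$id,
         tf = tf, occ = occ, num = Matrix::rowSums(occ), positions = positions),
    class = "kmer_vocab"
  )
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat(sprintf("<kmer_vocab> %d unique %d-mers over %d sequences\n",
              x$m, x$lenk, x$n))
  invisible(x)
}
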