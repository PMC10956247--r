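# motif extraction from trained embeddings: mutual-information scoring
# against shuffled negatives, seed expansion, background co-occurrence merge
# test, overlap merging, and PWM assembly

#' Mutual-information matrix between k-mer and sequence embeddings
#'
#' Scores each (k-mer, sequence) pair by the cosine similarity of its k-mer
#' embedding (a row of `Msc`) and sequence embedding (a row of `Esq`); the
#' two live in the same space because `dsq = dc + ds + dj`. Zero vectors give
#' 0. A plain dot product is available for sensitivity checks.
#'
#' @param kmer_emb Matrix of k-mer embeddings (rows: k-mers).
#' @param seq_emb Matrix of sequence embeddings (rows: sequences).
#' @param method `"cosine"` (default) or `"dot"`.
#' @return A `nrow(kmer_emb)` x `nrow(seq_emb)` score matrix.
#' @export
mutual_information <- function(kmer_emb, seq_emb, method = c("cosine", "dot")) {
  method <- match.arg(method)
  if (ncol(kmer_emb) != ncol(seq_emb)) {
    abort("k-mer and sequence embeddings have different widths; set dsq = dc + ds + dj")
  }
  if (method == "dot") return(tcrossprod(kmer_emb, seq_emb))
  normalize_rows <- function(x) {
    nrm <- sqrt(rowSums(x^2))
    keep <- nrm > 0
    x[keep, ] <- x[keep, , drop = FALSE] / nrm[keep]
    x
  }
  tcrossprod(normalize_rows(kmer_emb), normalize_rows(seq_emb))
}

#' Subtract the negative-set background noise from an MI matrix
#'
#' The grand mean of the negative-set MI matrix is the background noise
#' level; it is subtracted from every entry of the positive-set matrix.
#'
#' @param mi_pos MI matrix over positive-set k-mers and sequences.
#' @param mi_neg MI matrix over negative-set k-mers and sequences.
#' @return The denoised matrix, with the noise scalar attached as attribute
#'   `"noise"`.
#' @export
denoise_mi <- function(mi_pos, mi_neg) {
  if (length(mi_neg) == 0) abort("empty negative-set MI matrix: no negatives to estimate noise from")
  noise <- mean(mi_neg)
  structure(mi_pos - noise, noise = noise)
}

#' Expand seed k-mer occurrences into candidate binding-site intervals
#'
#' Around each seed occurrence starting at `start`, the center base is
#' `ck = start + ceiling((lenk - 1) / 2)`; the flanking k-mers are
#' `kl = [ck - lenk + 1, ck]` and `kr = [ck + 1, ck + lenk]`, and the
#' candidate site is their union `[ck - lenk + 1, ck + lenk]` of length
#' `2 * lenk`. Occurrences whose flanks leave the sequence are dropped.
#'
#' @param occurrences Tibble with `seq` (sequence index), `start` (1-based
#'   occurrence start) and optionally other columns, carried through.
#' @param lenk k-mer width.
#' @param seq_len Sequence length(s), recycled against rows.
#' @return The input rows that stay in bounds, with `ck`, `kl_start`,
#'   `kr_end` columns added.
#' @export
expand_seed <- function(occurrences, lenk, seq_len) {
  out <- occurrences |>
    mutate(ck = .data$start + ceiling((lenk - 1) / 2),
           kl_start = .data$ck - lenk + 1L,
           kr_end = .data$ck + lenk)
  keep <- out$kl_start >= 1 & out$kr_end <= seq_len
  if (any(!keep)) {
    inform(sprintf("skipped %d seed occurrence(s) whose expansion leaves the sequence",
                   sum(!keep)))
  }
  out[keep, , drop = FALSE]
}

#' Background co-occurrence merge test for flank k-mer pairs
#'
#' A candidate site is kept when its left and right flank k-mers are more
#' strongly associated in the positives than in the shuffled negatives:
#' accept iff `wco(kl, kr)` computed on positive-set counts is smaller than
#' `bwco(kl, kr)` computed on negative-set counts (smaller is stronger under
#' the negated-PMI sign convention). Pairs that never co-occur in the
#' negatives have `bwco = +Inf`, so any positive-set co-occurrence accepts;
#' pairs that never co-occur in the positives are rejected.
#'
#' @param kl,kr Character vectors of flank k-mers (recycled pairwise).
#' @param pos_vocab [kmer_vocabulary()] built from positive sequences only.
#' @param neg_vocab [kmer_vocabulary()] built from negative sequences only.
#' @return Logical vector: merge or not.
#' @export
coexist_test <- function(kl, kr, pos_vocab, neg_vocab) {
  wco <- pairwise_wco(kl, kr, pos_vocab)
  bwco <- pairwise_wco(kl, kr, neg_vocab)
  bwco[is.na(bwco)] <- Inf     # never co-occurs in negatives
  !is.na(wco) & wco < bwco
}

# negated-PMI weight for specific k-mer pairs under a vocabulary's counts;
# NA when either k-mer is absent or the pair never co-occurs
pairwise_wco <- function(a, b, vocab) {
  ia <- match(a, vocab$kmers)
  ib <- match(b, vocab$kmers)
  out <- rep(NA_real_, length(ia))
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok)) return(out)
  key <- paste(ia[ok], ib[ok])
  first <- !duplicated(key)
  ua <- ia[ok][first]
  ub <- ib[ok][first]
  occ_d <- as.matrix(vocab$occ)
  nums <- rowSums(occ_d[ua, , drop = FALSE] * occ_d[ub, , drop = FALSE])
  n <- vocab$n
  P <- vocab$num / n
  vals <- -log((nums / n) / (P[ua] * P[ub]))
  vals[nums == 0] <- NA_real_
  out[ok] <- vals[match(key, key[first])]
  out
}

#' Merge overlapping candidate intervals
#'
#' Intervals sharing at least one position are unioned transitively;
#' adjacent-but-not-overlapping intervals are kept separate. This is what
#' produces binding sites longer than `2 * lenk` and hence motifs of
#' different lengths.
#'
#' @param intervals Tibble with `seq`, `start`, `end` (1-based inclusive).
#' @return Tibble with `seq`, `start`, `end`, sorted and non-overlapping
#'   within each sequence.
#' @export
merge_overlaps <- function(intervals) {
  if (nrow(intervals) == 0) {
    return(tibble(seq = integer(), start = integer(), end = integer()))
  }
  intervals |>
    group_by(.data$seq) |>
    arrange(.data$start, .data$end, .by_group = TRUE) |>
    mutate(grp = cumsum(.data$start > lag(cummax(.data$end),
                                          default = -Inf))) |>
    group_by(.data$seq, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    dplyr::select("seq", "start", "end") |>
    arrange(.data$seq, .data$start)
}

#' Assemble position weight matrices from extracted binding sites
#'
#' Greedy align-and-cluster assembly. Sites are processed longest first; each
#' site is aligned (ungapped, all offsets, full containment of the shorter
#' sequence) against every existing cluster's consensus and joins the best
#' cluster whose mismatch fraction over the aligned overlap is at most
#' `max_mismatch`, otherwise it founds a new cluster whose frame is its own
#' sequence. A refinement pass re-aligns all sites against the final consensi.
#' Clusters with at least `min_sites` members become motifs: aligned base
#' counts plus a pseudocount, column-normalized by per-column coverage, with
#' sparsely covered frame edges (coverage below half the sites) trimmed.
#' Alignment rather than exact-position matching is what lets sites whose
#' merged windows start at different registers support one motif.
#'
#' @param tfbs Tibble with `subseq` (site sequence) plus any locating columns
#'   (`seq`, `start`, `end`), carried into the motif's member table.
#' @param min_sites Minimum supporting sites per motif (default 5).
#' @param pseudocount Added to every base count before normalization
#'   (default 0.25).
#' @param max_mismatch Maximum mismatch fraction against the cluster
#'   consensus over the aligned overlap (default 0.25).
#' @return A list of motifs, each a list with `pwm` (4 x L), `counts`,
#'   `coverage` (sites covering each column), `nsites`, `length`,
#'   `consensus`, `members` (the contributing rows of `tfbs` with their
#'   alignment `offset`), ordered by decreasing `nsites`.
#' @export
build_motifs <- function(tfbs, min_sites = 5, pseudocount = 0.25,
                         max_mismatch = 0.25) {
  if (nrow(tfbs) == 0) return(list())
  ord <- order(-nchar(tfbs$subseq), tfbs$subseq)
  clusters <- align_cluster_sites(tfbs$subseq[ord], max_mismatch)
  motifs <- list()
  for (cl in clusters) {
    nsites <- length(cl$rows)
    if (nsites < min_sites) next
    keep_cols <- which(cl$coverage >= nsites / 2)
    if (length(keep_cols) == 0) next
    span <- seq(min(keep_cols), max(keep_cols))
    if (length(span) < 4) next
    counts <- cl$counts[, span, drop = FALSE]
    coverage <- cl$coverage[span]
    pwm <- sweep(counts + pseudocount, 2, coverage + 4 * pseudocount, "/")
    members <- tfbs[ord[cl$rows], , drop = FALSE]
    members$offset <- cl$offsets - (min(keep_cols) - 1L)
    motifs[[length(motifs) + 1]] <- list(
      pwm = structure(pwm, class = c("pwm", "matrix")),
      counts = counts, coverage = coverage, nsites = nsites,
      length = length(span), consensus = pwm_consensus(pwm),
      members = members)
  }
  motifs[order(-vapply(motifs, function(mo) mo$nsites, numeric(1)))]
}

# greedy best-offset clustering of variable-length sites, longest first.
# each cluster keeps a fixed frame (the founder's length), integer-coded
# counts, per-column coverage, and a current consensus; mismatch is the
# fraction of mismatching bases over the aligned overlap
align_cluster_sites <- function(subseqs, max_mismatch, refine = TRUE) {
  ints <- lapply(strsplit(subseqs, ""), match, DNA_BASES)
  n <- length(ints)
  clusters <- list()
  best_fit <- function(site) {
    l <- length(site)
    best <- c(cluster = 0, offset = 0, rate = Inf)
    for (ci in seq_along(clusters)) {
      cons <- clusters[[ci]]$consensus
      Lf <- length(cons)
      if (Lf < l) next
      offs <- 0:(Lf - l)
      win <- matrix(cons[outer(seq_len(l), offs, "+")], nrow = l)
      mm <- colSums(win != site) / l
      o <- which.min(mm)
      if (mm[o] < best[["rate"]]) {
        best <- c(cluster = ci, offset = offs[o], rate = mm[o])
      }
    }
    best
  }
  add_to <- function(ci, site, off, row) {
    cl <- clusters[[ci]]
    cols <- off + seq_along(site)
    cl$counts[cbind(site, cols)] <- cl$counts[cbind(site, cols)] + 1L
    cl$coverage[cols] <- cl$coverage[cols] + 1L
    cl$consensus[cols] <- apply(cl$counts[, cols, drop = FALSE], 2, which.max)
    cl$rows <- c(cl$rows, row)
    cl$offsets <- c(cl$offsets, off)
    clusters[[ci]] <<- cl
  }
  new_cluster <- function(site, row) {
    Lf <- length(site)
    counts <- matrix(0L, 4, Lf, dimnames = list(DNA_BASES, NULL))
    counts[cbind(site, seq_len(Lf))] <- 1L
    clusters[[length(clusters) + 1]] <<- list(
      counts = counts, coverage = rep(1L, Lf), consensus = site,
      rows = row, offsets = 0L)
  }
  for (i in seq_len(n)) {
    fit <- best_fit(ints[[i]])
    if (fit["rate"] <= max_mismatch) add_to(fit["cluster"], ints[[i]],
                                            fit["offset"], i)
    else new_cluster(ints[[i]], i)
  }
  if (refine && length(clusters) > 1) {
    # freeze the consensi, empty the clusters, re-assign every site
    frames <- lapply(clusters, `[[`, "consensus")
    clusters <- list()
    for (f in frames) {
      Lf <- length(f)
      clusters[[length(clusters) + 1]] <- list(
        counts = matrix(0L, 4, Lf, dimnames = list(DNA_BASES, NULL)),
        coverage = rep(0L, Lf), consensus = f,
        rows = integer(), offsets = integer())
    }
    for (i in seq_len(n)) {
      fit <- best_fit(ints[[i]])
      if (fit["rate"] <= max_mismatch) add_to(fit["cluster"], ints[[i]],
                                              fit["offset"], i)
      else new_cluster(ints[[i]], i)
    }
    clusters <- purrr::keep(clusters, function(cl) length(cl$rows) > 0)
  }
  clusters
}

#' Discover motifs from a trained model
#'
#' Runs the full extraction pipeline on a fitted network: computes the
#' positive- and negative-set mutual-information matrices, denoises the
#' positive matrix by the negative grand mean, selects per-sequence seed
#' k-mers (strictly positive denoised MI), expands every seed occurrence
#' into a `2 * lenk` candidate site, keeps candidates passing the background
#' co-occurrence merge test, merges overlapping candidates into
#' variable-length binding sites, and assembles per-length PWMs.
#'
#' @param fit A [train_gnn()] result.
#' @param graph The [build_graph()] the model was trained on.
#' @param corpus The prepared corpus tibble (`id`, `seq`, `label`).
#' @param min_sites,pseudocount,max_mismatch Motif assembly knobs, see
#'   [build_motifs()].
#' @param mi_method MI scorer. `"saliency"` (default) scores a k-mer by its
#'   rectified, squared linearized contribution to the positive-class logit
#'   (`relu(Esc(p) . W_inclu w_out)^2`, constant across sequences): the
#'   information the k-mer carries about binding as read out by the trained
#'   network. Squaring makes the negative-set noise mean tail-weighted, so
#'   subtracting it retains only decisively informative k-mers. `"cosine"`
#'   and `"dot"` score embedding geometry directly, see
#'   [mutual_information()]; both are retained for sensitivity analyses but
#'   are far less selective on planted benchmarks.
#' @return An object of class `"motif_set"`: list with `motifs` (see
#'   [build_motifs()]), `tfbs` (tibble: `id`, `seq`, `start`, `end`,
#'   `subseq` of all merged binding sites), `noise` (the background MI
#'   level), and `params`.
#' @export
find_motifs <- function(fit, graph, corpus, min_sites = 5, pseudocount = 0.25,
                        max_mismatch = 0.25,
                        mi_method = c("saliency", "cosine", "dot")) {
  mi_method <- match.arg(mi_method)
  check_mi_dims(fit$dims)
  stopifnot(inherits(fit, "gnn_fit"), inherits(graph, "multiview_graph"))
  ord <- match(graph$seq_ids, corpus$id)
  if (anyNA(ord)) abort("graph sequence nodes and corpus ids do not match")
  corpus <- corpus[ord, , drop = FALSE]
  lenk <- graph$lenk

  pos <- corpus[corpus$label == 1, , drop = FALSE]
  neg <- corpus[corpus$label == 0, , drop = FALSE]
  if (nrow(neg) == 0) abort("motif discovery needs negative sequences for the background model")
  pos_vocab <- kmer_vocabulary(pos, lenk)
  neg_vocab <- kmer_vocabulary(neg, lenk)

  pos_rows <- match(pos_vocab$kmers, graph$vocab$kmers)
  neg_rows <- match(neg_vocab$kmers, graph$vocab$kmers)
  pos_cols <- which(corpus$label == 1)
  neg_cols <- which(corpus$label == 0)
  if (mi_method == "saliency") {
    s <- drop(fit$Msc %*% fit$state$Winclu_train %*% fit$state$w_out)
    mi_k <- pmax(s, 0)^2
    mi_pos <- matrix(mi_k[pos_rows], length(pos_rows), length(pos_cols))
    mi_neg <- matrix(mi_k[neg_rows], length(neg_rows), length(neg_cols))
  } else {
    mi_pos <- mutual_information(fit$Msc[pos_rows, , drop = FALSE],
                                 fit$Esq[pos_cols, , drop = FALSE], mi_method)
    mi_neg <- mutual_information(fit$Msc[neg_rows, , drop = FALSE],
                                 fit$Esq[neg_cols, , drop = FALSE], mi_method)
  }
  dn <- denoise_mi(mi_pos, mi_neg)
  noise <- attr(dn, "noise")

  # seed occurrences: k-mer occurrences in positive sequences with
  # strictly positive denoised MI
  occ <- pos_vocab$positions |>
    mutate(dnmi = dn[cbind(.data$kmer, .data$seq)]) |>
    filter(.data$dnmi > 0)
  seq_lens <- nchar(pos$seq)
  cand <- expand_seed(occ, lenk, seq_lens[occ$seq])
  if (nrow(cand) > 0) {
    kl_str <- substr(pos$seq[cand$seq], cand$kl_start, cand$ck)
    kr_str <- substr(pos$seq[cand$seq], cand$ck + 1, cand$kr_end)
    keep <- coexist_test(kl_str, kr_str, pos_vocab, neg_vocab)
    cand <- cand[keep, , drop = FALSE]
  }
  merged <- merge_overlaps(
    tibble(seq = cand$seq, start = cand$kl_start, end = cand$kr_end))
  tfbs <- merged |>
    mutate(id = pos$id[.data$seq],
           subseq = substr(pos$seq[.data$seq], .data$start, .data$end)) |>
    dplyr::select("id", "seq", "start", "end", "subseq")

  motifs <- build_motifs(tfbs, min_sites = min_sites,
                         pseudocount = pseudocount,
                         max_mismatch = max_mismatch)
  structure(
    list(motifs = motifs, tfbs = tfbs, noise = noise,
         params = list(lenk = lenk, min_sites = min_sites,
                       pseudocount = pseudocount,
                       max_mismatch = max_mismatch, mi_method = mi_method)),
    class = "motif_set"
  )
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("<motif_set> %d motif(s) from %d binding site(s); background MI %.4f\n",
              length(x$motifs), nrow(x$tfbs), x$noise))
  invisible(x)
}

#' Fraction of known intervals recovered by reported binding sites
#'
#' A ground-truth instance counts as recovered when at least one reported
#' site overlaps it by at least one base.
#'
#' @param truth Tibble with `id`, `start`, `end` (e.g.
#'   `simulate_corpus()$truth`).
#' @param tfbs Tibble with `id`, `start`, `end` (e.g. `motif_set$tfbs`).
#' @return A single number in `[0, 1]`.
#' @export
interval_recall <- function(truth, tfbs) {
  if (nrow(truth) == 0) return(NA_real_)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(tfbs$id == truth$id[i] &
          tfbs$start <= truth$end[i] &
          tfbs$end >= truth$start[i])
  }, logical(1))
  mean(hit)
}
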