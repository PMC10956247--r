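# corpus preparation: footprint windowing, shuffled negatives, paired
# train/val/test splitting, k-merization

#' Trim footprint intervals to fixed windows around their centers
#'
#' Each interval is replaced by a window of `2 * flank + 1` bases centered on
#' `floor((start + end) / 2)`; the default flank of 50 yields the 101 bp
#' windows used throughout the pipeline. Intervals whose window would leave
#' the contig are dropped with a warning.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based inclusive;
#'   see [read_bed()] for conversion from BED).
#' @param flank Bases added on each side of the center.
#' @param contig_lengths Optional named vector of contig lengths used for the
#'   bounds check; unnamed contigs are only checked against position 1.
#' @return Tibble with the same columns, all intervals of length
#'   `2 * flank + 1`.
#' @export
trim_footprint <- function(intervals, flank = 50, contig_lengths = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (!is_count(flank)) abort("`flank` must be a non-negative integer")
  out <- intervals |>
    mutate(center = floor((.data$start + .data$end) / 2),
           start = .data$center - flank,
           end = .data$center + flank) |>
    dplyr::select(-"center")
  ok <- out$start >= 1
  if (!is.null(contig_lengths)) {
    len <- unname(contig_lengths[out$chrom])
    ok <- ok & (is.na(len) | out$end <= len)
  }
  if (any(!ok)) {
    warn(sprintf("dropped %d footprint(s) whose %d bp window leaves the contig",
                 sum(!ok), 2 * flank + 1))
  }
  out[ok, , drop = FALSE]
}

#' Rank footprints by score and keep those confirmed by a second caller
#'
#' Sorts the primary footprints by score (descending; ties broken by contig
#' then start), keeps the `top_n` best, and retains only those overlapping at
#' least one secondary interval by at least one base. This is how footprints
#' from one caller are cross-validated against another before windowing.
#'
#' @param primary Tibble with `chrom`, `start`, `end`, `score` (1-based
#'   inclusive).
#' @param secondary Tibble with `chrom`, `start`, `end`.
#' @param top_n How many top-scored primary footprints to consider
#'   (default 1500).
#' @return The surviving primary intervals, ranked.
#' @export
rank_and_intersect_footprints <- function(primary, secondary, top_n = 1500) {
  if (!"score" %in% names(primary)) {
    abort("`primary` footprints must carry a numeric `score` column")
  }
  ranked <- primary |>
    arrange(desc(.data$score), .data$chrom, .data$start) |>
    head(top_n)
  keep <- vapply(seq_len(nrow(ranked)), function(i) {
    any(secondary$chrom == ranked$chrom[i] &
          secondary$start <= ranked$end[i] &
          secondary$end >= ranked$start[i])
  }, logical(1))
  if (!any(keep)) warn("no top-ranked footprints overlap the secondary set")
  ranked[keep, , drop = FALSE]
}

#' Shuffle the bases of each sequence
#'
#' Uniform random permutation of the bases within each string; the base
#' multiset (and therefore mono-nucleotide composition) is preserved exactly.
#' This is how negative sequences are built from positives, so positives and
#' negatives differ only in base order.
#'
#' @param seqs Character vector of sequences.
#' @param seed Integer seed.
#' @return Character vector of shuffled sequences.
#' @export
shuffle_bases <- function(seqs, seed = 1) {
  local_seed(seed, {
    vapply(seqs, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Assign paired train/validation/test splits
#'
#' Splits positive/negative pairs (not individual sequences) so that a
#' positive and its shuffled partner always land in the same split,
#' preventing composition leakage across splits.
#'
#' @param records Tibble with at least `id` and `paired_id`.
#' @param fractions Train/validation/test fractions summing to 1
#'   (default 0.8/0.1/0.1).
#' @param seed Integer seed.
#' @return `records` with a `split` column (`"train"`, `"val"`, `"test"`).
#' @export
assign_splits <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-9) abort("`fractions` must sum to 1")
  pos_ids <- records$id[records$label == 1]
  n_pairs <- length(pos_ids)
  if (n_pairs < 10) abort("need at least 10 positive/negative pairs to populate all three splits")
  n_train <- round(fractions[1] * n_pairs)
  n_val <- round(fractions[2] * n_pairs)
  if (n_train + n_val >= n_pairs) n_val <- max(1L, n_pairs - n_train - 1L)
  local_seed(seed, {
    perm <- sample(pos_ids)
    split_of <- setNames(
      rep(c("train", "val", "test"),
          c(n_train, n_val, n_pairs - n_train - n_val)),
      perm)
    records |>
      mutate(split = unname(
        split_of[ifelse(.data$label == 1, .data$id, .data$paired_id)]))
  })
}

#' Prepare a labeled, split, shuffled-negative corpus from positive sequences
#'
#' The full preprocessing contract in one call: drop sequences containing
#' non-ACGT letters (k-mer identity is undefined over N), uppercase, label
#' positives `1`, generate one base-shuffled negative (label `0`) per
#' positive, and assign paired 80/10/10 train/validation/test splits.
#'
#' @param sequences Tibble with `id`, `seq` (positives), e.g.
#'   `simulate_corpus()$sequences` or [read_fasta()] output.
#' @param fractions Split fractions, default `c(0.8, 0.1, 0.1)`.
#' @param seed Integer seed driving both the shuffles and the split.
#' @return Tibble with `id`, `seq`, `label`, `split`, `paired_id`; one row
#'   per sequence, negatives interleaved after their positives.
#' @examples
#' sim <- simulate_corpus(12, motifs = make_pwm(8, 2), seed = 1)
#' corpus <- prepare_corpus(sim$sequences, seed = 1)
#' table(corpus$label, corpus$split)
#' @export
prepare_corpus <- function(sequences, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  stopifnot(all(c("id", "seq") %in% names(sequences)))
  sequences <- mutate(sequences, seq = toupper(.data$seq))
  bad <- !is_acgt(sequences$seq)
  if (any(bad)) {
    inform(sprintf("dropped %d sequence(s) containing non-ACGT letters", sum(bad)))
    sequences <- sequences[!bad, , drop = FALSE]
  }
  if (nrow(sequences) == 0) abort("no usable sequences after filtering")
  neg <- tibble(
    id = paste0(sequences$id, "_shuf"),
    seq = shuffle_bases(sequences$seq, seed = seed),
    label = 0L,
    paired_id = sequences$id
  )
  pos <- tibble(id = sequences$id, seq = sequences$seq, label = 1L,
                paired_id = neg$id)
  corpus <- bind_rows(pos, neg) |>
    arrange(match(ifelse(.data$label == 1, .data$id, .data$paired_id),
                  sequences$id), desc(.data$label))
  assign_splits(corpus, fractions, seed = seed + 1L)
}

#' Enumerate the k-mers of a sequence
#'
#' Slides a width-`lenk` window along the sequence with step 1.
#'
#' @param seq A single sequence string.
#' @param lenk k-mer width in bases.
#' @return Tibble with `kmer` and `start` (1-based); exactly
#'   `nchar(seq) - lenk + 1` rows, empty (with a warning) if the sequence is
#'   shorter than `lenk`.
#' @examples
#' extract_kmers("ACGTAC", 5)
#' @export
extract_kmers <- function(seq, lenk) {
  L <- nchar(seq)
  if (L < lenk) {
    warn(sprintf("sequence of length %d is shorter than lenk = %d", L, lenk))
    return(tibble(kmer = character(), start = integer()))
  }
  starts <- seq_len(L - lenk + 1)
  tibble(kmer = substring(seq, starts, starts + lenk - 1), start = starts)
}
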