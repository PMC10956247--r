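# planted-motif corpus simulator: fixed-length DNA sequences carrying known
# motif instances, the ground truth against which discovery is scored

#' Simulate a planted-motif sequence corpus
#'
#' Generates `n_pos` fixed-length DNA sequences over an i.i.d. background and
#' plants, per sequence, a configurable number of motif instances sampled
#' column-wise from the supplied PWMs at non-overlapping uniform-random
#' positions. This emulates ATAC-seq footprint windows (101 bp around a
#' footprint center) in which one to a few binding sites sit on accessible
#' background; paired shuffled negatives are produced later by
#' [prepare_corpus()].
#'
#' @param n_pos Number of positive sequences.
#' @param seq_len Sequence length in bases (default 101, a footprint-centered
#'   window).
#' @param motifs A single PWM or list of PWMs (see [make_pwm()]); instances
#'   are drawn uniformly among them.
#' @param instances Integer range `c(min, max)` of motif instances per
#'   sequence (default 1-3).
#' @param background Base composition, a named probability vector over
#'   A/C/G/T (default uniform). With `markov_order = 1`, a 4 x 4 row-stochastic
#'   transition matrix may be supplied as `transition`.
#' @param markov_order 0 (i.i.d. background, the default and the matching null
#'   for base-shuffled negatives) or 1 (first-order Markov background).
#' @param transition Optional 4 x 4 transition matrix for `markov_order = 1`.
#' @param seed Integer seed; the same config and seed reproduce the corpus
#'   byte for byte.
#' @param max_tries Placement retries per sequence before giving up.
#' @return A list of class `"planted_corpus"`:
#'   * `sequences`: tibble with `id`, `seq`;
#'   * `truth`: tibble with `id`, `motif_id`, `start`, `end` (1-based
#'     inclusive coordinates of each planted instance);
#'   * `motifs`, `config`.
#' @examples
#' sim <- simulate_corpus(10, motifs = make_pwm(8, 2), seed = 1)
#' sim$truth
#' @export
simulate_corpus <- function(n_pos, seq_len = 101, motifs = list(),
                            instances = c(1, 3),
                            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                            markov_order = 0, transition = NULL,
                            seed = 1, max_tries = 200) {
  if (!is_count(n_pos) || n_pos < 1) abort("`n_pos` must be a positive integer")
  if (!is_count(seq_len) || seq_len < 1) abort("`seq_len` must be a positive integer")
  if (inherits(motifs, "pwm") || (is.matrix(motifs) && nrow(motifs) == 4)) {
    motifs <- list(motifs)
  }
  for (pwm in motifs) validate_pwm(pwm)
  if (length(instances) == 1) instances <- c(instances, instances)
  if (instances[1] < 0) abort("`instances` minimum must be >= 0")
  widths <- vapply(motifs, ncol, integer(1))
  if (length(motifs) > 0 && instances[2] > floor(seq_len / min(widths))) {
    abort("`instances` maximum exceeds floor(seq_len / min motif width)")
  }
  if (length(motifs) == 0 && instances[2] > 0) {
    abort("cannot plant instances without motifs; pass `motifs` or set instances to 0")
  }
  background <- background[DNA_BASES]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-9) {
    abort("`background` must be a probability vector named A, C, G, T")
  }

  local_seed(seed, {
    out <- purrr::map(seq_len(n_pos), function(i) {
      bases <- sample_background(seq_len, background, markov_order, transition)
      k <- if (instances[1] == instances[2]) instances[1] else
        sample(instances[1]:instances[2], 1)
      placed <- place_instances(seq_len, motifs, k, max_tries, i)
      if (nrow(placed) > 0) {
        for (r in seq_len(nrow(placed))) {
          pwm <- motifs[[placed$motif_id[r]]]
          inst <- vapply(seq_len(ncol(pwm)),
                         function(j) sample(DNA_BASES, 1, prob = pwm[, j]),
                         character(1))
          bases[placed$start[r]:placed$end[r]] <- inst
        }
      }
      list(seq = paste(bases, collapse = ""), truth = placed)
    })
    sequences <- tibble(
      id = sprintf("pos_%04d", seq_len(n_pos)),
      seq = purrr::map_chr(out, "seq")
    )
    truth <- purrr::map(out, "truth")
    truth <- dplyr::bind_rows(
      purrr::map2(truth, sequences$id, ~ dplyr::mutate(.x, id = .y))
    )
    if (nrow(truth) > 0) truth <- dplyr::select(truth, "id", "motif_id", "start", "end")
    structure(
      list(sequences = sequences, truth = truth, motifs = motifs,
           config = list(n_pos = n_pos, seq_len = seq_len,
                         instances = instances, background = background,
                         markov_order = markov_order, seed = seed)),
      class = "planted_corpus"
    )
  })
}

validate_pwm <- function(pwm) {
  if (!is.matrix(pwm) || nrow(pwm) != 4) abort("a PWM must be a 4-row matrix")
  if (ncol(pwm) < 4) abort("PWM width must be >= 4")
  if (any(abs(colSums(pwm) - 1) > 1e-9)) abort("every PWM column must sum to 1")
  invisible(pwm)
}

sample_background <- function(len, background, markov_order, transition) {
  if (markov_order == 0) {
    return(sample(DNA_BASES, len, replace = TRUE, prob = background))
  }
  if (is.null(transition)) {
    transition <- matrix(rep(background, each = 4), 4, 4,
                         dimnames = list(DNA_BASES, DNA_BASES))
  }
  bases <- character(len)
  bases[1] <- sample(DNA_BASES, 1, prob = background)
  for (i in seq_len(len - 1)) {
    bases[i + 1] <- sample(DNA_BASES, 1, prob = transition[bases[i], ])
  }
  bases
}

# draw k non-overlapping placements; bounded rejection sampling
place_instances <- function(seq_len, motifs, k, max_tries, seq_index) {
  empty <- tibble(motif_id = integer(), start = integer(), end = integer())
  if (k == 0) return(empty)
  for (try in seq_len(max_tries)) {
    ids <- sample.int(length(motifs), k, replace = TRUE)
    w <- vapply(motifs[ids], ncol, integer(1))
    starts <- vapply(w, function(wi) sample.int(seq_len - wi + 1, 1), integer(1))
    ends <- starts + w - 1L
    ord <- order(starts)
    if (k == 1 || all(starts[ord][-1] > ends[ord][-k])) {
      return(tibble(motif_id = ids, start = starts, end = ends))
    }
  }
  abort(sprintf(
    "could not place %d non-overlapping motif instances in a %d bp sequence (sequence %d) after %d tries; reduce `instances` or widen `seq_len`",
    k, seq_len, seq_index, max_tries))
}

#' Write a simulated corpus to disk
#'
#' Writes the positive sequences as FASTA and the ground truth as a BED-like
#' TSV (`id`, `start` 0-based, `end` half-open, `motif_id`). Internal
#' coordinates are 1-based inclusive; the file uses BED conventions.
#'
#' @param sim A `"planted_corpus"` from [simulate_corpus()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(sim, dir) {
  stopifnot(inherits(sim, "planted_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$sequences, file.path(dir, "positives.fa"))
  truth_bed <- sim$truth |>
    dplyr::transmute(.data$id, start = .data$start - 1L, end = .data$end,
                     motif_id = .data$motif_id)
  write_atomic(file.path(dir, "truth.tsv"), function(tmp) {
    readr::write_tsv(truth_bed, tmp)
  })
  invisible(dir)
}
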