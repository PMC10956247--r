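# position weight matrices: construction, information content, comparison

#' Build a random position weight matrix with a target information content
#'
#' Each column places probability `p` on one randomly chosen dominant base and
#' `(1 - p) / 3` on the rest, with `p` solved so that the column carries
#' exactly `ic_per_col` bits (`2 + sum(p * log2(p))` for a 4-letter alphabet).
#' Only the identity of the dominant base is random, so the realized mean
#' per-column information content equals the request.
#'
#' @param width Motif width in bases (>= 4).
#' @param ic_per_col Target information content per column, in bits (0-2).
#'   2 bits forces a point-mass column; 0 bits a uniform one.
#' @param seed Integer seed controlling the dominant-base draws.
#' @return A 4 x `width` probability matrix with rows A, C, G, T, class
#'   `"pwm"`; every column sums to 1.
#' @examples
#' pwm <- make_pwm(8, ic_per_col = 1.5, seed = 7)
#' mean(pwm_info_content(pwm))
#' @export
make_pwm <- function(width, ic_per_col = 1.5, seed = 1) {
  if (!is_count(width) || width < 4) abort("`width` must be an integer >= 4")
  if (!is.numeric(ic_per_col) || ic_per_col < 0 || ic_per_col > 2) {
    abort("`ic_per_col` must lie in [0, 2]: 2 bits is the maximum for a 4-letter alphabet")
  }
  p <- dominant_prob_for_ic(ic_per_col)
  local_seed(seed, {
    dominant <- sample.int(4L, width, replace = TRUE)
    pwm <- matrix((1 - p) / 3, nrow = 4, ncol = width,
                  dimnames = list(DNA_BASES, NULL))
    pwm[cbind(dominant, seq_len(width))] <- p
    structure(pwm, class = c("pwm", "matrix"))
  })
}

# solve 2 + p log2 p + (1-p) log2((1-p)/3) = ic for p in [0.25, 1]
dominant_prob_for_ic <- function(ic) {
  if (ic >= 2 - 1e-12) return(1)
  if (ic <= 1e-12) return(0.25)
  f <- function(p) {
    q <- (1 - p) / 3
    2 + p * log2(p) + 3 * q * ifelse(q > 0, log2(q), 0) - ic
  }
  uniroot(f, c(0.25 + 1e-9, 1 - 1e-9), tol = 1e-12)$root
}

#' Per-column information content of a PWM
#'
#' @param pwm A 4 x L probability matrix (rows A, C, G, T).
#' @return Numeric vector of length L, bits per column (`2 + sum(p log2 p)`).
#' @export
pwm_info_content <- function(pwm) {
  apply(pwm, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Consensus sequence of a PWM
#'
#' @param pwm A 4 x L probability matrix (rows A, C, G, T).
#' @return A single string; ties broken by alphabetical base order.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm, 2, which.max)], collapse = "")
}

#' Best-offset column-wise correlation between two PWMs
#'
#' Slides the narrower matrix along the wider one (no gaps, full overlap of
#' the narrower matrix required) and reports the offset maximizing the Pearson
#' correlation between the flattened overlapping columns. Used to score how
#' well a discovered motif recovers a known (planted) one.
#'
#' @param pwm A 4 x L probability matrix.
#' @param reference A second 4 x L' probability matrix.
#' @return A list with `r` (best Pearson correlation), `offset` (0-based shift
#'   of the narrower matrix within the wider one), and `width` (columns
#'   compared).
#' @export
pwm_similarity <- function(pwm, reference) {
  a <- unclass(pwm); b <- unclass(reference)
  if (ncol(a) < ncol(b)) { tmp <- a; a <- b; b <- tmp }
  w <- ncol(b)
  offsets <- 0:(ncol(a) - w)
  rs <- vapply(offsets, function(o) {
    x <- as.numeric(a[, (o + 1):(o + w)])
    y <- as.numeric(b)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(-1)
    cor(x, y)
  }, numeric(1))
  best <- which.max(rs)
  list(r = rs[best], offset = offsets[best], width = w)
}
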