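# shared fixtures and independent brute-force oracles

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_corpus <- function(n, len, seed) {
  withr::with_seed(seed, {
    tibble::tibble(id = sprintf("s%02d", seq_len(n)),
                   seq = vapply(rep(len, n), random_dna, character(1)))
  })
}

# brute-force k-mer statistics: plain loops and set operations, no matrix
# algebra shared with the implementation
oracle_kmer_stats <- function(seqs, lenk) {
  per_seq <- lapply(seqs, function(s) {
    if (nchar(s) < lenk) return(character(0))
    starts <- seq_len(nchar(s) - lenk + 1)
    substring(s, starts, starts + lenk - 1)
  })
  kmers <- sort(unique(unlist(per_seq)))
  n <- length(seqs)
  m <- length(kmers)
  occ_sets <- lapply(kmers, function(k) {
    which(vapply(per_seq, function(ks) k %in% ks, logical(1)))
  })
  tf <- matrix(0, m, n)
  for (i in seq_len(n)) {
    for (k in per_seq[[i]]) {
      p <- match(k, kmers)
      tf[p, i] <- tf[p, i] + 1
    }
  }
  list(kmers = kmers, n = n, m = m, occ_sets = occ_sets,
       num = lengths(occ_sets), tf = tf)
}

# brute-force O(m^2 n) recount of all four edge-weight matrices
oracle_graph <- function(seqs, lenk) {
  st <- oracle_kmer_stats(seqs, lenk)
  m <- st$m; n <- st$n
  Wco <- matrix(0, m, m)
  Wjac <- matrix(0, m, m)
  Wsim <- matrix(0, m, m)
  for (p in seq_len(m)) {
    for (j in seq_len(m)) {
      inter <- length(intersect(st$occ_sets[[p]], st$occ_sets[[j]]))
      uni <- length(union(st$occ_sets[[p]], st$occ_sets[[j]]))
      if (p != j && inter > 0) {
        P1 <- st$num[p] / n; P2 <- st$num[j] / n; Q <- inter / n
        Wco[p, j] <- -log(Q / (P1 * P2))
      }
      Wjac[p, j] <- inter / uni
      a <- strsplit(st$kmers[p], "")[[1]]
      b <- strsplit(st$kmers[j], "")[[1]]
      Wsim[p, j] <- sum(a != b)
    }
  }
  Winclu <- matrix(0, m, n)
  for (p in seq_len(m)) {
    for (i in seq_len(n)) {
      if (st$tf[p, i] > 0) {
        Winclu[p, i] <- st$tf[p, i] * log(n / st$num[p])
      }
    }
  }
  list(kmers = st$kmers, Wco = Wco, Wsim = Wsim, Wjac = Wjac, Winclu = Winclu)
}

# AUC by exhaustive positive/negative pair enumeration
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# small helper: a tiny trainable graph for gradient checks (too few pairs
# for prepare_corpus's split minimum, so the corpus is assembled by hand)
tiny_graph_fixture <- function(seed = 42, n_pairs = 4, len = 12, lenk = 3) {
  pos <- random_corpus(n_pairs, len, seed)
  corpus <- tibble::tibble(
    id = c(pos$id, paste0(pos$id, "_shuf")),
    seq = c(pos$seq, shuffle_bases(pos$seq, seed = seed)),
    label = rep(c(1L, 0L), each = n_pairs),
    split = rep(rep(c("train", "val", "test"),
                    c(n_pairs - 2, 1, 1)), 2),
    paired_id = c(paste0(pos$id, "_shuf"), pos$id))
  list(corpus = corpus, graph = build_graph(corpus, lenk))
}

# the planted-motif study corpus used by the training-sanity and
# motif-recovery checks; one full pipeline run per seed, cached so several
# tests can share it
planted_run_cache <- new.env(parent = emptyenv())

planted_run <- function(seed) {
  key <- as.character(seed)
  if (is.null(planted_run_cache[[key]])) {
    pwm <- make_pwm(8, ic_per_col = 1.8, seed = 11)
    sim <- simulate_corpus(150, seq_len = 101, motifs = pwm, seed = seed)
    corpus <- prepare_corpus(sim$sequences, seed = seed)
    graph <- build_graph(corpus, lenk = 5)
    fit <- train_gnn(graph, corpus, epochs = 30, seed = seed)
    motifs <- suppressMessages(find_motifs(fit, graph, corpus))
    planted_run_cache[[key]] <- list(pwm = pwm, sim = sim, corpus = corpus,
                                     graph = graph, fit = fit,
                                     motifs = motifs)
  }
  planted_run_cache[[key]]
}

# prepare_corpus emits an informational message when dropping records;
# wrapper keeping tests quiet where the message is not the point
quiet <- function(expr) suppressMessages(expr)
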