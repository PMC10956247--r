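# three-layer transductive GNN over the multi-view graph.
#
# layer 1 learns k-mer embeddings from the three k-mer views:
#   Eco  = ReLU(Ect  Wco  A_co),  A_co  m x dc   (A_* are trainable)
#   Esim = ReLU(Est  Wsim A_sim), A_sim m x ds
#   Ejac = ReLU(Ejt  Wjac A_jac), A_jac m x dj
# layer 2 pools k-mer embeddings into sequence embeddings via the inclusion
# view: Esq(i) = ReLU(Winclu[, i]' Msc A_inclu), Msc = [Eco | Esim | Ejac].
# layer 3 is a logistic read-out shared across sequence nodes.
#
# the whole graph (train + val + test sequence nodes) participates in the
# forward pass; only training nodes contribute loss and gradient.
# gradients are derived analytically (see backprop below) and checked against
# finite differences in the test suite.

#' Embedding dimensions of the network
#'
#' @param dc,ds,dj Widths of the co-occurrence, similarity and Jaccard k-mer
#'   embeddings (default 50 each).
#' @param dsq Width of the sequence embedding; must equal `dc + ds + dj`
#'   (default 150) so that k-mer and sequence embeddings share a space for
#'   the mutual-information stage.
#' @return A named list of class `"gnn_dims"`.
#' @export
gnn_dims <- function(dc = 50, ds = 50, dj = 50, dsq = dc + ds + dj) {
  if (any(c(dc, ds, dj, dsq) < 1)) abort("all embedding widths must be positive")
  structure(list(dc = dc, ds = ds, dj = dj, dsq = dsq), class = "gnn_dims")
}

check_mi_dims <- function(dims) {
  if (dims$dsq != dims$dc + dims$ds + dims$dj) {
    abort("motif discovery requires dsq = dc + ds + dj so k-mer and sequence embeddings are comparable; adjust `gnn_dims()`")
  }
}

#' Initialize trainable network weights
#'
#' All matrices are drawn from zero-mean normals with Glorot-style scale
#' `1 / sqrt(fan_in)`; the output bias starts at 0. Deterministic under
#' `seed`.
#'
#' @param m Number of k-mer nodes (graph vocabulary size).
#' @param dims A [gnn_dims()].
#' @param seed Integer seed.
#' @return A list of class `"gnn_state"` with `Wco_train` (m x dc),
#'   `Wsim_train` (m x ds), `Wjac_train` (m x dj), `Winclu_train`
#'   (D x dsq, D = dc+ds+dj), `w_out` (dsq), `b_out` (scalar).
#' @export
init_gnn_state <- function(m, dims = gnn_dims(), seed = 1) {
  if (!is_count(m) || m < 1) abort("`m` must be a positive integer")
  D <- dims$dc + dims$ds + dims$dj
  local_seed(seed, {
    structure(list(
      Wco_train = matrix(rnorm(m * dims$dc, sd = 1 / sqrt(m)), m, dims$dc),
      Wsim_train = matrix(rnorm(m * dims$ds, sd = 1 / sqrt(m)), m, dims$ds),
      Wjac_train = matrix(rnorm(m * dims$dj, sd = 1 / sqrt(m)), m, dims$dj),
      Winclu_train = matrix(rnorm(D * dims$dsq, sd = 1 / sqrt(D)), D, dims$dsq),
      w_out = rnorm(dims$dsq, sd = 1 / sqrt(dims$dsq)),
      b_out = 0
    ), class = "gnn_state", dims = dims)
  })
}

# fixed propagation operators: the products Ect Wco etc. never change during
# training, so they are computed once. the pooling operator is the transpose
# of Winclu with each sequence's weights L1-normalized, so a sequence
# embedding is a TF-IDF-weighted mean (not sum) of its k-mer embeddings —
# the same normalization the first layer applies to its views, and what
# keeps the logits on a trainable scale regardless of sequence length.
# each k-mer view's operator is further scaled to unit RMS so the three
# views enter the first layer on a common scale and the fixed epoch budget
# is spent fitting, not rescaling
graph_propagation <- function(graph) {
  rms_scale <- function(x) { r <- sqrt(mean(x^2)); if (r > 0) x / r else x }
  list(
    Bco = rms_scale(graph$Ect %*% graph$Wco),
    Bsim = rms_scale(graph$Est %*% graph$Wsim),
    Bjac = rms_scale(graph$Ejt %*% graph$Wjac),
    WincluT = row_normalize(as.matrix(Matrix::t(graph$Winclu)))
  )
}

#' Forward pass of the network
#'
#' @param graph A [build_graph()] result.
#' @param state A [init_gnn_state()] (or trained) parameter set.
#' @param prop Optional precomputed propagation operators (internal; used by
#'   the training loop to avoid recomputing fixed matrix products).
#' @return A list with the k-mer embedding matrix `Msc` (m x D, the stacked
#'   `Eco`/`Esim`/`Ejac`), the sequence embeddings `Esq` (n x dsq), the
#'   predicted probabilities `y_hat` (in (0,1)), and the pre-activations
#'   needed for backpropagation.
#' @export
gnn_forward <- function(graph, state, prop = NULL) {
  dims <- attr(state, "dims")
  if (nrow(state$Wco_train) != graph$m) {
    abort(sprintf("state was initialized for m = %d k-mer nodes but the graph has m = %d",
                  nrow(state$Wco_train), graph$m))
  }
  if (is.null(prop)) prop <- graph_propagation(graph)
  eco <- prop$Bco %*% state$Wco_train
  esim <- prop$Bsim %*% state$Wsim_train
  ejac <- prop$Bjac %*% state$Wjac_train
  Msc <- cbind(pmax(eco, 0), pmax(esim, 0), pmax(ejac, 0))
  pooled <- as.matrix(prop$WincluT %*% Msc)      # n x D
  esq <- pooled %*% state$Winclu_train           # n x dsq
  Esq <- pmax(esq, 0)
  z <- drop(Esq %*% state$w_out) + state$b_out
  list(Msc = Msc, Esq = Esq, y_hat = plogis(z),
       pre = list(eco = eco, esim = esim, ejac = ejac, esq = esq,
                  pooled = pooled))
}

#' Per-sequence binary cross-entropy
#'
#' Probabilities are clipped to `[1e-12, 1 - 1e-12]` before taking logs.
#'
#' @param y 0/1 labels.
#' @param y_hat Predicted probabilities.
#' @return Non-negative per-sequence losses.
#' @export
bce_loss <- function(y, y_hat) {
  p <- pmin(pmax(y_hat, 1e-12), 1 - 1e-12)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Iterative loss: current BCE plus the previous epoch's self-weighted BCE
#'
#' `iterloss = Dloss + bce` with `Dloss = prev_bce * sigmoid(prev_bce)`. The
#' previous-epoch term is a cached constant — no gradient flows through it —
#' so at epoch 1 (where the cached loss is defined to be 0) the iterative
#' loss reduces exactly to BCE.
#'
#' @param prev_bce Per-sequence BCE from the previous epoch (0 at epoch 1).
#' @param curr_bce Per-sequence BCE at the current epoch.
#' @return Per-sequence iterative losses.
#' @export
iter_loss <- function(prev_bce, curr_bce) {
  prev_bce * plogis(prev_bce) + curr_bce
}

# analytic gradients of mean BCE over training nodes w.r.t. all parameters.
# fwd must come from gnn_forward with the same prop.
gnn_backprop <- function(graph, state, prop, fwd, y, train_mask) {
  dims <- attr(state, "dims")
  n_train <- sum(train_mask)
  gz <- numeric(graph$n)
  gz[train_mask] <- (fwd$y_hat - y)[train_mask] / n_train
  g_wout <- drop(crossprod(fwd$Esq, gz))
  g_bout <- sum(gz)
  G_esq <- (gz %o% state$w_out) * (fwd$pre$esq > 0)        # n x dsq
  g_Winclu <- crossprod(fwd$pre$pooled, G_esq)             # D x dsq
  G_msc <- crossprod(prop$WincluT, G_esq %*% t(state$Winclu_train))  # m x D
  ic <- seq_len(dims$dc)
  is <- dims$dc + seq_len(dims$ds)
  ij <- dims$dc + dims$ds + seq_len(dims$dj)
  list(
    Wco_train = crossprod(prop$Bco, G_msc[, ic, drop = FALSE] * (fwd$pre$eco > 0)),
    Wsim_train = crossprod(prop$Bsim, G_msc[, is, drop = FALSE] * (fwd$pre$esim > 0)),
    Wjac_train = crossprod(prop$Bjac, G_msc[, ij, drop = FALSE] * (fwd$pre$ejac > 0)),
    Winclu_train = g_Winclu,
    w_out = g_wout,
    b_out = g_bout
  )
}

#' Train the network transductively
#'
#' Full-batch training on the whole graph: every epoch runs a forward pass
#' over all sequence nodes, computes the mean iterative loss over *training*
#' nodes only (validation and test nodes are masked — they contribute no
#' gradient, though their embeddings are computed), and takes one Adam step
#' with learning rate `lr * exp(-decay * (epoch - 1))`.
#'
#' @param graph A [build_graph()] of the full corpus.
#' @param corpus The prepared corpus tibble with `id`, `label`, `split`
#'   matching the graph's sequence nodes.
#' @param dims A [gnn_dims()].
#' @param epochs Number of epochs (default 30).
#' @param lr Initial learning rate (default 0.001).
#' @param decay Natural exponential decay rate of the learning rate
#'   (default 0.001).
#' @param loss `"iterloss"` (default) or plain `"bce"`.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `"gnn_fit"`: list with the trained `state`,
#'   `history` (tibble: epoch, lr, train_loss, val_auc), `predictions`
#'   (tibble: id, label, split, score), the final `Msc` and `Esq` embedding
#'   matrices, and the training configuration.
#' @examples
#' \donttest{
#' sim <- simulate_corpus(20, seq_len = 41, motifs = make_pwm(8, 2), seed = 1)
#' corpus <- prepare_corpus(sim$sequences, seed = 1)
#' graph <- build_graph(corpus, lenk = 5)
#' fit <- train_gnn(graph, corpus, dims = gnn_dims(8, 8, 8), epochs = 5)
#' tidy(fit)
#' }
#' @export
train_gnn <- function(graph, corpus, dims = gnn_dims(), epochs = 30,
                      lr = 0.001, decay = 0.001,
                      loss = c("iterloss", "bce"), seed = 1) {
  loss <- match.arg(loss)
  if (!is_count(epochs) || epochs < 1) abort("`epochs` must be >= 1")
  if (lr <= 0) abort("`lr` must be positive")
  stopifnot(all(c("id", "label", "split") %in% names(corpus)))
  ord <- match(graph$seq_ids, corpus$id)
  if (anyNA(ord)) abort("graph sequence nodes and corpus ids do not match")
  y <- corpus$label[ord]
  split <- corpus$split[ord]
  train_mask <- split == "train"
  if (!any(train_mask)) abort("no training sequences in the corpus")

  prop <- graph_propagation(graph)
  state <- init_gnn_state(graph$m, dims, seed)
  opt <- adam_init(state)
  prev_bce <- numeric(graph$n)    # cached per-sequence BCE; 0 before epoch 1
  history <- vector("list", epochs)

  for (e in seq_len(epochs)) {
    lr_e <- lr * exp(-decay * (e - 1))
    fwd <- gnn_forward(graph, state, prop)
    curr_bce <- bce_loss(y, fwd$y_hat)
    per_seq <- if (loss == "iterloss") iter_loss(prev_bce, curr_bce) else curr_bce
    train_loss <- mean(per_seq[train_mask])
    val_mask <- split == "val"
    val_auc <- if (any(val_mask) && length(unique(y[val_mask])) == 2) {
      auc_roc(y[val_mask], fwd$y_hat[val_mask])
    } else NA_real_
    history[[e]] <- tibble(epoch = e, lr = lr_e, train_loss = train_loss,
                           val_auc = val_auc)
    grads <- gnn_backprop(graph, state, prop, fwd, y, train_mask)
    upd <- adam_step(state, grads, opt, lr_e, e)
    state <- upd$state
    opt <- upd$opt
    prev_bce <- curr_bce
  }

  fwd <- gnn_forward(graph, state, prop)
  structure(
    list(state = state, dims = dims,
         history = dplyr::bind_rows(history),
         predictions = tibble(id = graph$seq_ids, label = y, split = split,
                              score = fwd$y_hat),
         Msc = fwd$Msc, Esq = fwd$Esq,
         config = list(epochs = epochs, lr = lr, decay = decay, loss = loss,
                       seed = seed, lenk = graph$lenk)),
    class = "gnn_fit"
  )
}

# Adam with beta1 = 0.9, beta2 = 0.999, eps = 1e-8
adam_init <- function(state) {
  zeros <- purrr::map(unclass(state), function(p) p * 0)
  list(m = zeros, v = zeros)
}

adam_step <- function(state, grads, opt, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^t)
    vhat <- opt$v[[nm]] / (1 - beta2^t)
    state[[nm]] <- state[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, opt = opt)
}

#' @export
print.gnn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<gnn_fit> %d epochs (%s); train loss %.4f -> %.4f; final val AUC %.3f\n",
    nrow(h), x$config$loss, h$train_loss[1], h$train_loss[nrow(h)],
    h$val_auc[nrow(h)]))
  invisible(x)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint bundles the trained parameters, dimensions, configuration
#' and history in a single RDS archive; `history` is additionally written as
#' a TSV alongside.
#'
#' @param fit A `"gnn_fit"`.
#' @param path Checkpoint file path (`.rds`).
#' @return `path` (write) / the restored `"gnn_fit"` (read).
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "gnn_fit"))
  write_atomic(path, function(tmp) saveRDS(fit, tmp))
  readr::write_tsv(fit$history, paste0(tools::file_path_sans_ext(path),
                                       "_history.tsv"))
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "gnn_fit"))
  fit
}
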