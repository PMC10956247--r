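# config-driven hyperparameter sweep: train once per grid row, report
# validation AUC

#' Grid-search hyperparameters by validation AUC
#'
#' Trains one model per grid row and reports the final validation AUC for
#' each combination. Columns may be any of `lenk`, `dc`, `ds`, `dj`,
#' `epochs`, `lr`, `decay`, `loss`; missing columns fall back to the
#' defaults. The graph is rebuilt only when `lenk` changes.
#'
#' @param corpus A prepared corpus tibble ([prepare_corpus()]).
#' @param grid Tibble of hyperparameter combinations (e.g. from
#'   [tidyr::expand_grid()]).
#' @param seed Integer seed shared by all runs.
#' @return `grid` with a `val_auc` column appended, sorted best-first.
#' @export
sweep_hyperparams <- function(corpus, grid, seed = 1) {
  defaults <- list(lenk = 5L, dc = 50L, ds = 50L, dj = 50L, epochs = 30L,
                   lr = 0.001, decay = 0.001, loss = "iterloss")
  graphs <- new.env(parent = emptyenv())
  val_auc <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    p <- utils::modifyList(defaults, as.list(grid[i, , drop = FALSE]))
    key <- as.character(p$lenk)
    if (is.null(graphs[[key]])) graphs[[key]] <- build_graph(corpus, p$lenk)
    fit <- train_gnn(graphs[[key]], corpus,
                     dims = gnn_dims(p$dc, p$ds, p$dj),
                     epochs = p$epochs, lr = p$lr, decay = p$decay,
                     loss = p$loss, seed = seed)
    fit$history$val_auc[nrow(fit$history)]
  })
  grid |>
    mutate(val_auc = val_auc) |>
    arrange(desc(val_auc))
}
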