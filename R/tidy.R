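# broom-style summaries and ggplot2 visualizations of fitted objects

#' Tidy a trained model: the per-epoch training history
#'
#' @param x A `"gnn_fit"`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `lr`, `train_loss`, `val_auc`.
#' @method tidy gnn_fit
#' @export
tidy.gnn_fit <- function(x, ...) x$history

#' One-row summary of a trained model
#'
#' @param x A `"gnn_fit"`.
#' @param ... Unused.
#' @return Tibble with epochs, final training loss, final validation AUC,
#'   and test AUC (NA if the corpus has no test split).
#' @method glance gnn_fit
#' @export
glance.gnn_fit <- function(x, ...) {
  test <- filter(x$predictions, .data$split == "test")
  test_auc <- if (nrow(test) > 0 && length(unique(test$label)) == 2) {
    auc_roc(test$label, test$score)
  } else NA_real_
  tibble(epochs = nrow(x$history),
         train_loss = x$history$train_loss[nrow(x$history)],
         val_auc = x$history$val_auc[nrow(x$history)],
         test_auc = test_auc)
}

#' Tidy a motif set: one row per motif
#'
#' @param x A `"motif_set"`.
#' @param ... Unused.
#' @return Tibble with `motif`, `length`, `nsites`, `consensus`,
#'   `ic_per_col` (mean bits per column).
#' @method tidy motif_set
#' @export
tidy.motif_set <- function(x, ...) {
  if (length(x$motifs) == 0) {
    return(tibble(motif = integer(), length = integer(), nsites = integer(),
                  consensus = character(), ic_per_col = numeric()))
  }
  tibble(
    motif = seq_along(x$motifs),
    length = vapply(x$motifs, function(mo) mo$length, numeric(1)),
    nsites = vapply(x$motifs, function(mo) mo$nsites, numeric(1)),
    consensus = vapply(x$motifs, function(mo) mo$consensus, character(1)),
    ic_per_col = vapply(x$motifs,
                        function(mo) mean(pwm_info_content(mo$pwm)),
                        numeric(1)))
}

#' One-row summary of a motif set
#'
#' @param x A `"motif_set"`.
#' @param ... Unused.
#' @return Tibble with motif and site counts, distinct site lengths, and the
#'   background MI level.
#' @method glance motif_set
#' @export
glance.motif_set <- function(x, ...) {
  tibble(n_motifs = length(x$motifs), n_tfbs = nrow(x$tfbs),
         n_lengths = dplyr::n_distinct(x$tfbs$end - x$tfbs$start + 1),
         noise = x$noise)
}

#' Training-history curves
#'
#' @param object A `"gnn_fit"`.
#' @param ... Unused.
#' @return A ggplot: training loss and validation AUC against epoch.
#' @method autoplot gnn_fit
#' @export
autoplot.gnn_fit <- function(object, ...) {
  df <- object$history |>
    tidyr::pivot_longer(c("train_loss", "val_auc"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Information-content profiles of discovered motifs
#'
#' A compact logo substitute: per-column stacked base probabilities scaled by
#' column information content.
#'
#' @param object A `"motif_set"`.
#' @param top Plot at most this many motifs (by support), default 6.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot motif_set
#' @export
autoplot.motif_set <- function(object, top = 6, ...) {
  motifs <- head(object$motifs, top)
  if (length(motifs) == 0) abort("no motifs to plot")
  df <- purrr::imap(motifs, function(mo, i) {
    ic <- pwm_info_content(mo$pwm)
    as_tibble(as.data.frame.table(unclass(mo$pwm),
                                  responseName = "prob")) |>
      mutate(base = rep(DNA_BASES, mo$length),
             position = rep(seq_len(mo$length), each = 4),
             bits = .data$prob * ic[.data$position],
             motif = sprintf("motif %d (n=%d)", i, mo$nsites))
  }) |> bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$bits,
                                   fill = .data$base)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~motif, scales = "free_x") +
    ggplot2::labs(x = "position", y = "bits") +
    ggplot2::theme_minimal()
}

#' Radar plot of an evaluation report
#'
#' @param report Output of [evaluate_predictions()].
#' @return A ggplot of the eight-spoke metric polygon whose area is the
#'   radar summary score.
#' @export
plot_metrics_radar <- function(report) {
  verts <- radar_vertices(report)
  poly <- bind_rows(verts, verts[1, ])
  ggplot2::ggplot(poly, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(alpha = 0.3) +
    ggplot2::geom_point(data = verts) +
    ggplot2::geom_text(data = verts,
                       ggplot2::aes(label = .data$metric),
                       nudge_x = 0.08, nudge_y = 0.08, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
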