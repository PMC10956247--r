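# classifier evaluation: confusion counts, six threshold metrics, ROC/PR
# areas, and the eight-spoke radar-area summary

#' Confusion counts at a probability threshold
#'
#' A prediction is called positive when its score is `>= threshold` (ties go
#' to the positive class).
#'
#' @param labels 0/1 labels.
#' @param scores Predicted probabilities.
#' @param threshold Binarization threshold in (0, 1), default 0.5.
#' @return One-row tibble with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  if (length(labels) == 0) abort("cannot tally an empty prediction set")
  if (length(labels) != length(scores)) abort("`labels` and `scores` lengths differ")
  stopifnot_scalar_prob(threshold, "threshold")
  pred <- scores >= threshold
  tibble(tp = sum(pred & labels == 1), tn = sum(!pred & labels == 0),
         fp = sum(pred & labels == 0), fn = sum(!pred & labels == 1))
}

#' Threshold classification metrics from confusion counts
#'
#' Computes precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, their harmonic mean
#' F1, accuracy, specificity `TN/(FP+TN)`, and the Matthews correlation
#' coefficient. A metric whose denominator is zero is reported as 0 and
#' flagged `undefined`, so the radar area stays computable.
#'
#' @param counts One-row tibble from [confusion_counts()] (or any list with
#'   `tp`, `tn`, `fp`, `fn`).
#' @return Tibble with `metric`, `value`, `undefined`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (tp + tn + fp + fn == 0) abort("empty confusion counts")
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (precision$value > 0 && recall$value > 0) {
    list(value = 2 * precision$value * recall$value /
           (precision$value + recall$value), undefined = FALSE)
  } else list(value = 0, undefined = TRUE)
  acc <- list(value = (tp + tn) / (tp + tn + fp + fn), undefined = FALSE)
  spec <- safe_div(tn, fp + tn)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) list(value = 0, undefined = TRUE) else
    list(value = (tp * tn - fp * fn) / mcc_den, undefined = FALSE)
  vals <- list(precision = precision, recall = recall, f1 = f1, acc = acc,
               specificity = spec, mcc = mcc)
  tibble(metric = names(vals),
         value = unname(vapply(vals, `[[`, numeric(1), "value")),
         undefined = unname(vapply(vals, `[[`, logical(1), "undefined")))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic via mid-ranks:
#' `P(score+ > score-) + 0.5 * P(tie)`.
#'
#' @param labels 0/1 labels; both classes must be present.
#' @param scores Prediction scores.
#' @return A value in `[0, 1]`.
#' @export
auc_roc <- function(labels, scores) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("AUC requires both classes to be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (rectangular) interpolation over the ranked precision-recall
#' points, processing tied scores as blocks; this avoids the optimism of
#' trapezoidal PR interpolation.
#'
#' @param labels 0/1 labels; at least one positive required.
#' @param scores Prediction scores.
#' @return A value in `(0, 1]`.
#' @export
auc_pr <- function(labels, scores) {
  P <- sum(labels == 1)
  if (P == 0) abort("PR area requires at least one positive")
  ord <- order(scores, decreasing = TRUE)
  df <- tibble(score = scores[ord], y = labels[ord]) |>
    group_by(.data$score) |>
    summarise(pos = sum(.data$y == 1), tot = n(), .groups = "drop") |>
    arrange(desc(.data$score)) |>
    mutate(cum_tp = cumsum(.data$pos), cum_n = cumsum(.data$tot),
           precision = .data$cum_tp / .data$cum_n,
           recall = .data$cum_tp / P)
  sum(df$precision * (df$recall - lag(df$recall, default = 0)))
}

#' Radar-area summary of the eight metrics
#'
#' Places the eight metrics (precision, recall, F1, accuracy, specificity,
#' MCC, ROC AUC, PR AUC) on eight equiangular spokes and sums the areas of
#' the eight triangles between consecutive spokes:
#' `sum over i of 0.5 * R_i * R_{i+1} * sin(pi/4)` with the ninth spoke
#' wrapping back to precision. The maximum (all metrics 1) is `2 * sqrt(2)`.
#' A negative MCC enters the formula literally (signed triangle) and is
#' flagged, since a radar chart cannot display a negative radius.
#'
#' @param metrics Named numeric vector or one-column tibble/list containing
#'   `precision`, `recall`, `f1`, `acc`, `specificity`, `mcc`, `auc`, `prc`.
#' @return The radar area, with attribute `"negative_mcc"` when MCC < 0.
#' @export
aemr <- function(metrics) {
  want <- c("precision", "recall", "f1", "acc", "specificity", "mcc",
            "auc", "prc")
  if (is.data.frame(metrics)) {
    metrics <- setNames(metrics$value, metrics$metric)
  }
  metrics <- unlist(metrics)[want]
  if (anyNA(metrics)) abort("all eight metrics are required for the radar area")
  R <- c(metrics, metrics[1])
  area <- sum(0.5 * R[1:8] * R[2:9] * sin(pi / 4))
  structure(area, negative_mcc = metrics[["mcc"]] < 0)
}

#' Evaluate predictions with the full metric suite
#'
#' Computes the six threshold metrics, ROC and PR areas, and the radar-area
#' summary from a predictions table.
#'
#' @param predictions Tibble with `label` and `score` columns (e.g.
#'   `gnn_fit$predictions`, optionally filtered to one split).
#' @param threshold Binarization threshold, default 0.5.
#' @return Tibble with `metric`, `value`, `undefined` — nine rows ending in
#'   `aemr`.
#' @examples
#' evaluate_predictions(tibble::tibble(label = c(1, 1, 0, 0),
#'                                     score = c(0.9, 0.4, 0.6, 0.1)))
#' @export
evaluate_predictions <- function(predictions, threshold = 0.5) {
  stopifnot(all(c("label", "score") %in% names(predictions)))
  cc <- confusion_counts(predictions$label, predictions$score, threshold)
  base <- classification_metrics(cc)
  extra <- tibble(
    metric = c("auc", "prc"),
    value = c(auc_roc(predictions$label, predictions$score),
              auc_pr(predictions$label, predictions$score)),
    undefined = FALSE)
  full <- bind_rows(base, extra)
  a <- aemr(full)
  bind_rows(full, tibble(metric = "aemr", value = as.numeric(a),
                         undefined = isTRUE(attr(a, "negative_mcc"))))
}

#' Radar-polygon vertices for a metrics report
#'
#' @param report The output of [evaluate_predictions()] (the `aemr` row is
#'   ignored).
#' @return Tibble with `metric`, `value`, `x`, `y` — the eight polygon
#'   vertices on equiangular spokes.
#' @export
radar_vertices <- function(report) {
  eight <- filter(report, .data$metric != "aemr")
  angle <- pi / 2 - (seq_len(8) - 1) * pi / 4
  mutate(eight, x = .data$value * cos(angle), y = .data$value * sin(angle))
}
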