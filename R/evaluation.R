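#' Residue-level confusion counts against interval annotations
#'
#' Disordered is the positive class: TP are residues both predicted and
#' annotated disordered, FN predicted ordered but annotated disordered,
#' TN both ordered, FP predicted disordered but annotated ordered.
#' Residues annotated in neither class are excluded from scoring.
#'
#' @param prediction A `disorder_prediction` (or tibble with a logical
#'   `label` column, one row per residue).
#' @param annotations Interval rows for this protein: `start`, `end`,
#'   `label` in `{"disordered", "ordered"}`.
#' @return One-row tibble `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_counts <- function(prediction, annotations) {
  n <- nrow(prediction)
  truth <- annotation_truth(annotations, n)
  scored <- !is.na(truth)
  pred_dis <- prediction$label[scored]
  true_dis <- truth[scored] == "disordered"
  tibble(
    tp = sum(pred_dis & true_dis),
    fn = sum(!pred_dis & true_dis),
    tn = sum(!pred_dis & !true_dis),
    fp = sum(pred_dis & !true_dis)
  )
}

## accept a one-row tibble or a named vector of counts
as_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- as.list(counts)
  list(
    tp = as.numeric(counts$tp), fn = as.numeric(counts$fn),
    tn = as.numeric(counts$tn), fp = as.numeric(counts$fp)
  )
}

#' Plain residue accuracy ACCp
#'
#' `ACCp = (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts Confusion counts ([confusion_counts()] row or named
#'   list).
#' @return Accuracy in `[0, 1]`; `NA` with a warning when no residue was
#'   scored.
#' @export
acc_p <- function(counts) {
  ct <- as_counts(counts)
  total <- ct$tp + ct$tn + ct$fp + ct$fn
  if (total == 0) {
    warn("no scored residues: ACCp undefined")
    return(NA_real_)
  }
  (ct$tp + ct$tn) / total
}

#' Balanced accuracy ACCw
#'
#' `ACCw = (TP/(TP + FN) + TN/(TN + FP)) / 2`, the balanced mean of
#' sensitivity and specificity; it reflects accuracy over both the
#' disordered and the ordered parts of a sequence.
#'
#' @inheritParams acc_p
#' @return Balanced accuracy; `NA` with a warning when either class is
#'   absent from the annotation.
#' @export
acc_w <- function(counts) {
  ct <- as_counts(counts)
  if (ct$tp + ct$fn == 0 || ct$tn + ct$fp == 0) {
    warn("a class is missing from the annotation: ACCw undefined")
    return(NA_real_)
  }
  (ct$tp / (ct$tp + ct$fn) + ct$tn / (ct$tn + ct$fp)) / 2
}

#' Sweep the disorder-probability threshold
#'
#' Pools residues over proteins (micro-averaging: counts are summed
#' before the metrics) and evaluates ACCp and ACCw on a grid of
#' probability thresholds. Residues are labelled disordered when
#' `probability >= theta`.
#'
#' @param residues Tibble with columns `probability` and `truth`
#'   (`"disordered"` / `"ordered"`; other values are excluded), pooled
#'   over the protein set. See [pool_predictions()].
#' @param thetas Numeric threshold grid.
#' @return Tibble of class `acc_sweep`: `theta`, `tp`, `fn`, `tn`, `fp`,
#'   `acc_p`, `acc_w`, with attributes `best_accp` and `best_accw` (the
#'   argmax thresholds, first grid point on ties).
#' @export
threshold_sweep <- function(residues, thetas = seq(0, 1, by = 0.01)) {
  residues <- residues |> filter(truth %in% c("disordered", "ordered"))
  if (nrow(residues) == 0) {
    abort("no annotated residues to sweep", class = "admap_error_evaluation")
  }
  true_dis <- residues$truth == "disordered"
  out <- map_dfr(thetas, function(th) {
    pred <- residues$probability >= th
    tibble(
      theta = th,
      tp = sum(pred & true_dis), fn = sum(!pred & true_dis),
      tn = sum(!pred & !true_dis), fp = sum(pred & !true_dis)
    )
  }) |>
    mutate(
      acc_p = (tp + tn) / (tp + tn + fp + fn),
      acc_w = ifelse(
        tp + fn > 0 & tn + fp > 0,
        (tp / (tp + fn) + tn / (tn + fp)) / 2,
        NA_real_
      )
    )
  attr(out, "best_accp") <- out$theta[which.max(out$acc_p)]
  attr(out, "best_accw") <- out$theta[which.max(out$acc_w)]
  class(out) <- c("acc_sweep", class(out))
  out
}

#' @describeIn threshold_sweep Best thresholds and their metrics.
#' @param x An `acc_sweep`.
#' @param ... Unused.
#' @method glance acc_sweep
#' @export
glance.acc_sweep <- function(x, ...) {
  tibble(
    best_theta_accp = attr(x, "best_accp"),
    best_accp = max(x$acc_p, na.rm = TRUE),
    best_theta_accw = attr(x, "best_accw"),
    best_accw = max(x$acc_w, na.rm = TRUE)
  )
}

#' @method autoplot acc_sweep
#' @export
autoplot.acc_sweep <- function(object, ...) {
  df <- bind_rows(
    tibble(theta = object$theta, acc = object$acc_p, metric = "ACCp"),
    tibble(theta = object$theta, acc = object$acc_w, metric = "ACCw")
  )
  ggplot(df, aes(theta, acc, colour = metric)) +
    geom_line(na.rm = TRUE) +
    labs(x = "disorder probability threshold", y = "accuracy") +
    theme_minimal()
}

#' @export
plot.acc_sweep <- function(x, ...) print(autoplot(x, ...))

#' Pool predicted probabilities with their annotations
#'
#' Convenience builder for [threshold_sweep()] and evaluation reports:
#' joins each prediction's per-residue probabilities with the truth labels
#' from the interval annotations.
#'
#' @param predictions Named list of `disorder_prediction` objects (names
#'   are protein ids) or a single prediction.
#' @param annotations Tibble `protein_id`, `start`, `end`, `label`.
#' @return Tibble `protein_id`, `index`, `probability`, `label`, `truth`.
#' @export
pool_predictions <- function(predictions, annotations) {
  if (inherits(predictions, "disorder_prediction")) {
    predictions <- setNames(list(predictions), attr(predictions, "id"))
  }
  imap(predictions, function(pred, pid) {
    truth <- annotation_truth(
      annotations |> filter(protein_id == pid), nrow(pred)
    )
    tibble(
      protein_id = pid, index = pred$index,
      probability = pred$probability, label = pred$label, truth = truth
    )
  }) |> list_rbind()
}

#' Evaluate predictions per protein and pooled
#'
#' @inheritParams pool_predictions
#' @return Tibble with one row per protein plus a final `"pooled"` row:
#'   confusion counts and both accuracy measures (metrics are `NA` where
#'   undefined).
#' @export
evaluate_disorder <- function(predictions, annotations) {
  if (inherits(predictions, "disorder_prediction")) {
    predictions <- setNames(list(predictions), attr(predictions, "id"))
  }
  per <- imap(predictions, function(pred, pid) {
    ct <- confusion_counts(pred, annotations |> filter(protein_id == pid))
    mutate(ct, protein_id = pid, .before = 1)
  }) |> list_rbind()
  pooled <- per |>
    summarise(
      protein_id = "pooled",
      tp = sum(tp), fn = sum(fn), tn = sum(tn), fp = sum(fp)
    )
  bind_rows(per, pooled) |>
    rowwise() |>
    mutate(
      acc_p = suppressWarnings(acc_p(list(tp = tp, fn = fn, tn = tn, fp = fp))),
      acc_w = suppressWarnings(acc_w(list(tp = tp, fn = fn, tn = tn, fp = fp)))
    ) |>
    ungroup()
}
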