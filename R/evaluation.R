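# Multilabel evaluation: per-label confusion counts, precision/recall,
# average precision and mAP, micro/macro-F1, and the label-wise prediction
# confidence grid.

#' Per-label confusion counts at a confidence threshold
#'
#' Predictions are binarised per label with the strict rule
#' `predicted positive iff confidence > threshold` (a confidence exactly at
#' the threshold counts as negative).
#'
#' @param y_true N x C 0/1 matrix of ground-truth labels.
#' @param scores N x C matrix of confidences in `[0, 1]`.
#' @param threshold Scalar in (0, 1); default 0.5.
#' @return Data frame with one row per label: `label`, `TP`, `FP`, `FN`,
#'   `TN`, `threshold`.
#' @export
confusion_counts <- function(y_true, scores, threshold = 0.5) {
  y_true <- as.matrix(y_true); scores <- as.matrix(scores)
  if (!all(dim(y_true) == dim(scores))) {
    stop(sprintf("shape mismatch: y_true is %s, scores is %s",
                 paste(dim(y_true), collapse = "x"),
                 paste(dim(scores), collapse = "x")), call. = FALSE)
  }
  stopifnot(threshold > 0, threshold < 1)
  pred <- scores > threshold
  labels <- colnames(y_true) %||% paste0("label", seq_len(ncol(y_true)))
  data.frame(
    label = labels,
    TP = colSums(pred & y_true == 1),
    FP = colSums(pred & y_true == 0),
    FN = colSums(!pred & y_true == 1),
    TN = colSums(!pred & y_true == 0),
    threshold = threshold,
    row.names = NULL
  )
}

#' Per-label precision and recall from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`. A 0/0 ratio is
#' reported as 0 with the corresponding `*_undefined` flag set, so aggregate
#' means stay defined.
#'
#' @param counts Data frame from [confusion_counts()].
#' @return The counts with columns `precision`, `recall`,
#'   `precision_undefined`, `recall_undefined` appended.
#' @export
precision_recall <- function(counts) {
  pd <- counts$TP + counts$FP
  rd <- counts$TP + counts$FN
  counts$precision <- ifelse(pd > 0, counts$TP / pd, 0)
  counts$recall <- ifelse(rd > 0, counts$TP / rd, 0)
  counts$precision_undefined <- pd == 0
  counts$recall_undefined <- rd == 0
  counts
}

#' Average precision of a ranked score vector
#'
#' Area under the precision-recall curve computed as the mean, over the
#' positives in descending-score order, of the running precision at each
#' positive (every-point interpolation). Ties are broken by a stable sort of
#' descending score, so equal scores keep their input order.
#'
#' @param scores Numeric vector of confidences.
#' @param y_true 0/1 vector of the same length with at least one positive.
#' @return AP in `[0, 1]`.
#' @export
#' @examples
#' average_precision(c(0.9, 0.8, 0.3), c(1, 0, 1))  # (1 + 2/3) / 2
average_precision <- function(scores, y_true) {
  if (length(scores) != length(y_true)) {
    stop("scores and y_true must have the same length", call. = FALSE)
  }
  npos <- sum(y_true == 1)
  if (npos == 0) {
    stop("average precision is undefined without positive samples",
         call. = FALSE)
  }
  ord <- order(-scores)         # stable in R: ties keep input order
  ys <- y_true[ord]
  cum_tp <- cumsum(ys)
  prec_at_pos <- cum_tp[ys == 1] / which(ys == 1)
  mean(prec_at_pos)
}

#' Mean average precision
#'
#' @param aps Nonempty numeric vector of per-label APs in `[0, 1]`.
#' @return mAP as a percentage.
#' @export
map_score <- function(aps) {
  if (length(aps) == 0) stop("no APs supplied", call. = FALSE)
  100 * mean(aps)
}

#' Micro- and macro-averaged F1 scores
#'
#' Macro-F1 is the mean of per-label F1 scores; micro-F1 is the F1 of the
#' globally pooled TP/FP/FN counts.
#'
#' @param counts Data frame from [confusion_counts()].
#' @return List with `micro` and `macro` in `[0, 1]`.
#' @export
f1_scores <- function(counts) {
  f1 <- function(tp, fp, fn) {
    denom <- 2 * tp + fp + fn
    ifelse(denom > 0, 2 * tp / denom, 0)
  }
  macro <- mean(f1(counts$TP, counts$FP, counts$FN))
  micro <- f1(sum(counts$TP), sum(counts$FP), sum(counts$FN))
  list(micro = micro, macro = macro)
}

#' Evaluate a model on labelled images
#'
#' Computes the full evaluation report: per-label AP, mAP, per-label
#' precision/recall at the threshold, and micro/macro-F1. All values are
#' reported as percentages.
#'
#' @param model A trained `farnet_model`.
#' @param images H x W x 3 x N image array, pixels in `[0, 1]`.
#' @param y_true N x C 0/1 matrix (columns ordered like `model$labels`).
#' @param threshold Binarisation threshold for the counting metrics.
#' @return Object of class `farnet_eval_report`: list with `per_label`
#'   (data.frame of label, AP %, precision %, recall %, counts), `map_pct`,
#'   `micro_f1_pct`, `macro_f1_pct`, `threshold`, `confidence` (the N x C
#'   confidence matrix).
#' @export
evaluate_model <- function(model, images, y_true, threshold = 0.5) {
  pred <- predict_farnet(model, images)
  conf <- pred$confidence
  y_true <- as.matrix(y_true)
  counts <- precision_recall(confusion_counts(y_true, conf, threshold))
  aps <- vapply(seq_len(ncol(y_true)), function(l) {
    average_precision(conf[, l], y_true[, l])
  }, numeric(1))
  per_label <- data.frame(
    label = model$labels,
    ap_pct = 100 * aps,
    precision_pct = 100 * counts$precision,
    recall_pct = 100 * counts$recall,
    counts[, c("TP", "FP", "FN", "TN",
               "precision_undefined", "recall_undefined")],
    row.names = NULL
  )
  f1 <- f1_scores(counts)
  structure(list(per_label = per_label, map_pct = map_score(aps),
                 micro_f1_pct = 100 * f1$micro,
                 macro_f1_pct = 100 * f1$macro,
                 threshold = threshold, confidence = conf,
                 attention = pred$attention),
            class = "farnet_eval_report")
}

#' @export
print.farnet_eval_report <- function(x, ...) {
  cat("Multilabel evaluation (threshold", x$threshold, ")\n")
  tab <- x$per_label
  tab$ap_pct <- sprintf("%.2f", tab$ap_pct)
  tab$precision_pct <- sprintf("%.2f", tab$precision_pct)
  tab$recall_pct <- sprintf("%.2f", tab$recall_pct)
  print(tab[, c("label", "ap_pct", "precision_pct", "recall_pct")],
        row.names = FALSE)
  cat(sprintf("mAP %.2f%%  micro-F1 %.2f%%  macro-F1 %.2f%%\n",
              x$map_pct, x$micro_f1_pct, x$macro_f1_pct))
  invisible(x)
}

#' Label-wise prediction confidence grid
#'
#' Selects the confidence columns of the requested labels (by default the
#' four most frequent defect labels: russeting, mild rot, cracking, peeling)
#' into an N x k matrix suitable for a pairwise scatter grid.
#'
#' @param confidence N x C confidence matrix with label column names.
#' @param labels Character vector of labels to keep (k <= C).
#' @return Object of class `farnet_confidence_grid` (the N x k matrix).
#' @export
confidence_grid <- function(confidence, labels = c("r", "mr", "c", "p")) {
  unknown <- setdiff(labels, colnames(confidence))
  if (length(unknown)) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  grid <- confidence[, labels, drop = FALSE]
  class(grid) <- c("farnet_confidence_grid", class(grid))
  grid
}

#' Plot a confidence grid as a k x k pairwise scatter matrix
#'
#' Diagonal panels show per-label confidence histograms; off-diagonal panels
#' scatter one label's confidence against another's, optionally coloured by
#' ground truth of the row label.
#'
#' @param x A `farnet_confidence_grid`.
#' @param y_true Optional N x C 0/1 matrix used to colour points by the
#'   row-label ground truth.
#' @param file Optional PNG path; when given the figure is written there.
#' @param ... Unused.
#' @return The grid, invisibly.
#' @export
plot.farnet_confidence_grid <- function(x, y_true = NULL, file = NULL,
                                        ...) {
  labs <- colnames(x)
  k <- length(labs)
  if (!is.null(file)) {
    grDevices::png(file, width = 200 * k, height = 200 * k)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mfrow = c(k, k), mar = c(2, 2, 1.2, 0.5))
  on.exit(graphics::par(op), add = TRUE)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) {
        graphics::hist(x[, i], breaks = seq(0, 1, 0.05), main = labs[i],
                       xlab = "", ylab = "", col = "grey70", border = NA)
      } else {
        col <- if (!is.null(y_true)) {
          ifelse(y_true[, labs[i]] == 1, "#d95f02", "#7570b3")
        } else "#555555"
        graphics::plot(x[, j], x[, i], xlim = c(0, 1), ylim = c(0, 1),
                       pch = 16, cex = 0.4, col = col,
                       xlab = labs[j], ylab = labs[i],
                       main = paste(labs[i], "vs", labs[j]), cex.main = 0.8)
      }
    }
  }
  invisible(x)
}
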