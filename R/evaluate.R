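# Precision-recall machinery. auPRC uses the average-precision (step)
# integration convention: summing precision at each distinct score
# threshold weighted by the recall increment. Step integration avoids the
# optimistic interpolation of trapezoidal PR areas, and its baseline under
# uninformative scores equals the positive-class prevalence.

#' Area under the precision-recall curve
#'
#' Average-precision formulation: thresholds descend over the distinct
#' scores (ties grouped into one threshold), and the area is
#' \eqn{\sum_i (R_i - R_{i-1}) P_i} over the resulting PR points.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1, logical, or `"positive"`/`"negative"`).
#' @return List with `auprc`, the PR point table `points`
#'   (threshold/precision/recall), and the `prevalence` baseline.
#' @examples
#' auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auprc # 0.8333...
#' @export
auprc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stop_if(length(unique(y)) < 2L, "both classes must be present")
  stop_if(length(scores) != length(y), "scores and labels differ in length")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y[ord]
  # group ties: cumulative counts at the last index of each distinct score
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  npos <- sum(y)
  precision <- tp / (tp + fp)
  recall <- tp / npos
  dr <- diff(c(0, recall))
  list(auprc = sum(dr * precision),
       points = data.frame(threshold = s[last], precision = precision,
                           recall = recall),
       prevalence = npos / length(y))
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "positive")
  } else {
    as.integer(labels != 0)
  }
}

#' F-score threshold scan
#'
#' Computes F1 at each grid threshold (prediction = score >= threshold) and
#' returns the argmax, ties broken toward the larger threshold. Undefined
#' precision (no predicted positives) yields F = 0. This is the procedure
#' used to pick an operating threshold for genome-wide prediction.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels.
#' @param grid Threshold grid; default all distinct scores plus 0 and 1.
#' @return List with `best_threshold`, `best_f` and the scan table `scan`.
#' @export
f_score_threshold_scan <- function(scores, labels, grid = NULL) {
  y <- as_binary_labels(labels)
  if (is.null(grid)) grid <- sort(unique(c(0, 1, scores)))
  stop_if(length(grid) == 0L, "threshold grid is empty")
  f <- vapply(grid, function(t) {
    pred <- scores >= t
    tp <- sum(pred & y == 1L)
    if (tp == 0L) return(0)
    prec <- tp / sum(pred)
    rec <- tp / sum(y == 1L)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  best <- max(which(f == max(f)))
  list(best_threshold = grid[best], best_f = f[best],
       scan = data.frame(threshold = grid, f_score = f))
}

#' Confusion matrix at a threshold
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels.
#' @param threshold Decision threshold; prediction = score >= threshold.
#' @return Named integer vector `c(TP, FP, TN, FN)`; the four counts
#'   partition the input.
#' @export
confusion_at <- function(scores, labels, threshold) {
  y <- as_binary_labels(labels)
  pred <- scores >= threshold
  c(TP = sum(pred & y == 1L), FP = sum(pred & y == 0L),
    TN = sum(!pred & y == 0L), FN = sum(!pred & y == 1L))
}

#' Within/across-sample auPRC matrix
#'
#' Entry (i, j) is the auPRC of model i scored on dataset j; the diagonal
#' is the within-sample performance. Datasets are lists with elements
#' `features` (matrix) and `labels`; models must carry a `predict` method
#' over such feature matrices (see [train_gb()]). A feature-space mismatch
#' marks the entry `NA` rather than silently scoring.
#'
#' @param models Named list of trained models.
#' @param datasets Named list of datasets (`features`, `labels`).
#' @return Numeric matrix with model rows and dataset columns.
#' @export
cross_sample_matrix <- function(models, datasets) {
  out <- matrix(NA_real_, nrow = length(models), ncol = length(datasets),
                dimnames = list(names(models), names(datasets)))
  for (i in seq_along(models)) {
    for (j in seq_along(datasets)) {
      ds <- datasets[[j]]
      scores <- tryCatch(stats::predict(models[[i]], ds$features),
                         error = function(e) NULL)
      if (!is.null(scores)) out[i, j] <- auprc(scores, ds$labels)$auprc
    }
  }
  out
}
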