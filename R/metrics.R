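# Confusion-count-based evaluation metrics: dice, Jaccard/IoU, accuracy,
# precision, recall; per-image and per-class reports. All metrics derive
# from the TP/TN/FP/FN tallies of a binary ground-truth/prediction pair
# (soft predictions must be thresholded first).

#' Confusion counts of a binary mask pair
#'
#' Set-cardinality tallies `TP = |GT & PR|`, `TN = |!GT & !PR|`,
#' `FP = |!GT & PR|`, `FN = |GT & !PR|`; they always sum to the number of
#' pixels.
#'
#' @param gt,pr binary arrays/matrices of identical shape with values in
#'   {0, 1}.
#' @return one-row tibble with integer columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(gt, pr) {
  if (!identical(dim(gt), dim(pr)) || length(gt) != length(pr)) {
    abort("`gt` and `pr` must have identical shapes")
  }
  if (!all(gt %in% c(0, 1)) || !all(pr %in% c(0, 1))) {
    abort("masks must be binary; threshold soft predictions first")
  }
  g <- as.logical(gt)
  p <- as.logical(pr)
  tibble::tibble(tp = sum(g & p), tn = sum(!g & !p),
                 fp = sum(!g & p), fn = sum(g & !p))
}

#' Segmentation metrics from confusion counts
#'
#' `dsc()` is `2TP / (2TP + FP + FN)`, `iou()` is `TP / (TP + FP + FN)`
#' (so `DSC = 2 IoU / (1 + IoU)`), and `accuracy()`, `precision()`,
#' `recall()` follow the usual tallies. All are vectorised over the rows of
#' a counts tibble. Empty-mask convention: when both masks are empty
#' (`TP = FP = FN = 0`) DSC and IoU are 1; when exactly one is empty they
#' are 0. The same monotone convention applies to zero-denominator
#' precision and recall.
#'
#' @param counts tibble or list with fields `tp`, `tn`, `fp`, `fn`.
#' @return numeric vector in `[0, 1]`.
#' @name segmentation-metrics
NULL

#' @rdname segmentation-metrics
#' @export
dsc <- function(counts) {
  with(counts, ifelse(2 * tp + fp + fn == 0, 1, 2 * tp / (2 * tp + fp + fn)))
}

#' @rdname segmentation-metrics
#' @export
iou <- function(counts) {
  with(counts, ifelse(tp + fp + fn == 0, 1, tp / (tp + fp + fn)))
}

#' @rdname segmentation-metrics
#' @export
accuracy <- function(counts) {
  with(counts, (tp + tn) / (tp + tn + fp + fn))
}

#' @rdname segmentation-metrics
#' @export
precision <- function(counts) {
  with(counts, ifelse(tp + fp == 0, as.numeric(fn == 0), tp / (tp + fp)))
}

#' @rdname segmentation-metrics
#' @export
recall <- function(counts) {
  with(counts, ifelse(tp + fn == 0, as.numeric(fp == 0), tp / (tp + fn)))
}

metric_cols <- function(counts) {
  tibble::tibble(accuracy = accuracy(counts), precision = precision(counts),
                 recall = recall(counts), dice = dsc(counts),
                 jaccard = iou(counts))
}

#' Threshold / argmax decision rules
#'
#' `threshold_mask()` binarises a sigmoid probability map at `threshold`
#' (default 0.5); `argmax_mask()` reduces a softmax map `(H, W, M, N)` to
#' integer labels `0..M-1` by the per-pixel channel argmax.
#'
#' @param p probability array.
#' @param threshold decision threshold in `[0, 1]`.
#' @return array of the same spatial shape; binary or integer labels.
#' @export
threshold_mask <- function(p, threshold = 0.5) {
  (p >= threshold) * 1
}

#' @rdname threshold_mask
#' @export
argmax_mask <- function(p) {
  d <- dim(p)
  flat <- aperm(p, c(3, 1, 2, 4))
  lab <- apply(array(flat, c(d[3], d[1] * d[2] * d[4])), 2, which.max) - 1
  array(lab, c(d[1], d[2], 1, d[4]))
}

#' Per-class report for multi-class label masks
#'
#' One-vs-rest confusion counts and metrics per class, plus a final
#' `"macro"` row holding the unweighted means across classes (background,
#' class 0, can be excluded from the macro average).
#'
#' @param gt,pr integer label arrays of identical shape with values in
#'   `0..num_classes-1`.
#' @param num_classes number of classes M.
#' @param include_background include class 0 in the macro means.
#' @return tibble with one row per class plus the macro row; columns
#'   `class`, `tp`, `tn`, `fp`, `fn`, `accuracy`, `precision`, `recall`,
#'   `dice`, `jaccard`.
#' @export
multiclass_report <- function(gt, pr, num_classes, include_background = TRUE) {
  if (any(gt < 0) || any(gt > num_classes - 1) ||
      any(pr < 0) || any(pr > num_classes - 1)) {
    abort("labels out of range 0..num_classes-1")
  }
  rows <- lapply(seq_len(num_classes) - 1, function(m) {
    cc <- confusion_counts((gt == m) * 1, (pr == m) * 1)
    dplyr::bind_cols(tibble::tibble(class = as.character(m)), cc,
                     metric_cols(cc))
  })
  per_class <- dplyr::bind_rows(rows)
  keep <- if (include_background) seq_len(num_classes) else seq_len(num_classes)[-1]
  macro <- per_class[keep, c("accuracy", "precision", "recall", "dice", "jaccard")]
  macro_row <- dplyr::bind_cols(
    tibble::tibble(class = "macro", tp = NA_integer_, tn = NA_integer_,
                   fp = NA_integer_, fn = NA_integer_),
    dplyr::summarise(macro, dplyr::across(dplyr::everything(), mean))
  )
  dplyr::bind_rows(per_class, macro_row)
}

#' Per-image evaluation of predicted probability maps
#'
#' Applies the decision rule (threshold for one-channel sigmoid maps,
#' argmax otherwise), tallies per-image confusion counts against the
#' ground-truth masks, and appends a summary row with the mean of each
#' per-image metric (the box-plot-style aggregation; pooled-count
#' aggregation is available via `aggregate = "pooled"`).
#'
#' @param prob probability array `(H, W, M, N)`.
#' @param masks label array `(H, W, 1, N)` (binary or integer labels).
#' @param threshold decision threshold for the sigmoid case.
#' @param aggregate `"mean"` of per-image metrics (default) or `"pooled"`
#'   counts for the summary row.
#' @param include_background for multi-class inputs, include class 0 in the
#'   per-image macro dice.
#' @return tibble with one row per image plus a `"summary"` row.
#' @export
evaluate_predictions <- function(prob, masks, threshold = 0.5,
                                 aggregate = c("mean", "pooled"),
                                 include_background = FALSE) {
  aggregate <- match.arg(aggregate)
  d <- dim(prob)
  M <- d[3]
  n <- d[4]
  pred <- if (M == 1) threshold_mask(prob, threshold) else argmax_mask(prob)
  rows <- lapply(seq_len(n), function(i) {
    g <- masks[, , 1, i]
    p <- pred[, , 1, i]
    if (M == 1) {
      cc <- confusion_counts(g, p)
      dplyr::bind_cols(tibble::tibble(image = as.character(i)), cc,
                       metric_cols(cc))
    } else {
      rep_i <- multiclass_report(g, p, M, include_background)
      macro <- rep_i[rep_i$class == "macro", ]
      macro$class <- NULL
      dplyr::bind_cols(tibble::tibble(image = as.character(i)), macro)
    }
  })
  per_image <- dplyr::bind_rows(rows)
  metric_names <- c("accuracy", "precision", "recall", "dice", "jaccard")
  if (aggregate == "mean" || M > 1) {
    summ <- dplyr::summarise(per_image[, metric_names],
                             dplyr::across(dplyr::everything(), mean))
    summary_row <- dplyr::bind_cols(
      tibble::tibble(image = "summary", tp = NA_integer_, tn = NA_integer_,
                     fp = NA_integer_, fn = NA_integer_),
      summ)
  } else {
    pooled <- tibble::tibble(tp = sum(per_image$tp), tn = sum(per_image$tn),
                             fp = sum(per_image$fp), fn = sum(per_image$fn))
    summary_row <- dplyr::bind_cols(tibble::tibble(image = "summary"), pooled,
                                    metric_cols(pooled))
  }
  dplyr::bind_rows(per_image, summary_row)
}
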