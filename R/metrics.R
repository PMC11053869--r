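#' Intersection-over-union of two binary masks
#'
#' Ratio of the overlap area to the union area of two pixel sets on the same
#' grid; 0 when both masks are empty.
#'
#' @param a,b Logical (or 0/1) matrices of identical dimensions.
#' @return A value in [0, 1].
#' @export
mask_iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("mask dimensions differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  }
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Match predicted instances to ground truth
#'
#' One-to-one assignment of predictions to ground-truth masks: predictions
#' are visited in descending score order and greedily take the unmatched
#' ground truth of highest IoU, provided that IoU strictly exceeds the
#' threshold.  At `iou_threshold >= 0.5` the matching is unique regardless of
#' visiting order (no two instances can each overlap the same counterpart by
#' more than half the union), the standard panoptic-matching argument.
#'
#' @param predictions List of detections (each `list(mask, score)` or a bare
#'   mask; bare masks get score 1 in list order).
#' @param truths List of ground-truth masks.
#' @param iou_threshold Match threshold in (0, 1); default 0.5.
#' @return A `match_table`: list with `pairs` (data frame: prediction, truth,
#'   iou), `fp` and `fn` index vectors, counts `tp`, `fp_count`, `fn_count`,
#'   `tn_count` (recorded as 0; unused by the metrics) and `iou_threshold`.
#' @export
match_instances <- function(predictions, truths, iou_threshold = 0.5) {
  preds <- normalize_predictions(predictions)
  np <- length(preds); nt <- length(truths)
  iou <- matrix(0, nrow = np, ncol = nt)
  for (i in seq_len(np)) {
    for (j in seq_len(nt)) iou[i, j] <- mask_iou(preds[[i]]$mask, truths[[j]])
  }
  scores <- vapply(preds, function(p) p$score, numeric(1))
  order_p <- if (np) order(-scores) else integer(0)
  taken <- logical(nt)
  pairs <- list()
  matched_p <- logical(np)
  for (i in order_p) {
    if (nt == 0L) break
    cand <- which(!taken & iou[i, ] > iou_threshold)
    if (!length(cand)) next
    j <- cand[which.max(iou[i, cand])]
    taken[j] <- TRUE
    matched_p[i] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(prediction = i, truth = j,
                                              iou = iou[i, j])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(prediction = integer(), truth = integer(), iou = numeric())
  structure(list(pairs = pairs,
                 fp = which(!matched_p),
                 fn = which(!taken),
                 tp = nrow(pairs),
                 fp_count = sum(!matched_p),
                 fn_count = sum(!taken),
                 tn_count = 0L,
                 iou_threshold = iou_threshold),
            class = "match_table")
}

#' Precision, recall and count-based Dice from a match table
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `dice = 2 TP / (2 TP + FN + FP)`, each over instance counts and defined as
#' 0 when its denominator is 0.
#'
#' @param table A [match_instances()] result.
#' @return Named list `precision`, `recall`, `dice`.
#' @export
precision_recall_dice <- function(table) {
  tp <- table$tp; fp <- table$fp_count; fn <- table$fn_count
  list(precision = safe_div(tp, tp + fp),
       recall = safe_div(tp, tp + fn),
       dice = safe_div(2 * tp, 2 * tp + fn + fp))
}

#' Pixel-level Dice over matched instances
#'
#' The segmentation-flavoured companion of the count-based Dice: for each
#' matched pair, `2 |x n y| / (|x| + |y|)` over pixels, averaged over matched
#' pairs (0 with no matches).  Exposed separately because published Dice
#' values for segmentation benchmarks are often pixel-based.
#'
#' @param predictions,truths As in [match_instances()].
#' @param iou_threshold Match threshold.
#' @return A value in [0, 1].
#' @export
pixel_dice <- function(predictions, truths, iou_threshold = 0.5) {
  preds <- normalize_predictions(predictions)
  tab <- match_instances(preds, truths, iou_threshold)
  if (tab$tp == 0L) return(0)
  mean(vapply(seq_len(nrow(tab$pairs)), function(k) {
    a <- preds[[tab$pairs$prediction[k]]]$mask > 0
    b <- truths[[tab$pairs$truth[k]]] > 0
    2 * sum(a & b) / (sum(a) + sum(b))
  }, numeric(1)))
}

#' Average precision by confidence sweeping
#'
#' Sweeps the detection confidence over all distinct scores at a fixed IoU
#' threshold, computes the (recall, precision) point at each cutoff, and
#' integrates the all-point-interpolated (monotonized) precision over recall.
#' With `average_over_ious = TRUE` the AP is additionally averaged over IoU
#' thresholds 0.50 to 0.95 in steps of 0.05 (the COCO convention).
#'
#' @param predictions List of scored detections (`list(mask, score)`).
#' @param truths List of ground-truth masks.
#' @param iou_threshold IoU threshold deciding hits.
#' @param average_over_ious Average over the 0.50:0.05:0.95 IoU grid instead?
#' @return List with `ap` and `curve` (data frame recall/precision, one row
#'   per prediction in descending score order; for the averaged mode the
#'   curve of the 0.5 threshold).
#' @export
average_precision <- function(predictions, truths, iou_threshold = 0.5,
                              average_over_ious = FALSE) {
  if (average_over_ious) {
    thr <- seq(0.5, 0.95, by = 0.05)
    aps <- vapply(thr, function(t) {
      average_precision(predictions, truths, t)$ap
    }, numeric(1))
    base <- average_precision(predictions, truths, 0.5)
    return(list(ap = mean(aps), curve = base$curve))
  }
  preds <- normalize_predictions(predictions)
  nt <- length(truths)
  if (nt == 0L || length(preds) == 0L) {
    return(list(ap = 0, curve = data.frame(recall = numeric(),
                                           precision = numeric())))
  }
  scores <- vapply(preds, function(p) p$score, numeric(1))
  ord <- order(-scores)
  taken <- logical(nt)
  hit <- logical(length(preds))
  # Greedy in descending score order: a prediction scores a hit on the best
  # still-unmatched truth with IoU above threshold.  Strictly-greater keeps
  # the rule consistent with match_instances.
  for (i in ord) {
    ious <- vapply(seq_len(nt), function(j) {
      if (taken[j]) -1 else mask_iou(preds[[i]]$mask, truths[[j]])
    }, numeric(1))
    j <- which.max(ious)
    if (ious[j] > iou_threshold) {
      taken[j] <- TRUE
      hit[i] <- TRUE
    }
  }
  h <- hit[ord]
  tp <- cumsum(h)
  fp <- cumsum(!h)
  recall <- tp / nt
  precision <- tp / (tp + fp)
  prec_interp <- rev(cummax(rev(precision)))
  ap <- sum(diff(c(0, recall)) * prec_interp)
  list(ap = ap, curve = data.frame(recall = recall, precision = precision))
}

#' Panoptic quality
#'
#' `DQ = TP / (TP + FN/2 + FP/2)` (detection quality), `SQ` = mean IoU over
#' matched pairs (0 with no matches; segmentation quality), `PQ = DQ * SQ`.
#'
#' @inheritParams average_precision
#' @return Named list `pq`, `dq`, `sq`.
#' @export
panoptic_quality <- function(predictions, truths, iou_threshold = 0.5) {
  tab <- match_instances(predictions, truths, iou_threshold)
  dq <- safe_div(tab$tp, tab$tp + tab$fn_count / 2 + tab$fp_count / 2)
  sq <- if (tab$tp > 0L) mean(tab$pairs$iou) else 0
  list(pq = dq * sq, dq = dq, sq = sq)
}

#' Full evaluation report for one run
#'
#' Computes precision, recall, count-based Dice, average precision, DQ, SQ
#' and PQ for a set of predictions against ground truth at one IoU threshold.
#'
#' @inheritParams average_precision
#' @return A `metrics_report`: list of the metric values plus the
#'   recall--precision `curve` and the underlying `match_table`.
#' @export
evaluate_detections <- function(predictions, truths, iou_threshold = 0.5) {
  tab <- match_instances(predictions, truths, iou_threshold)
  prd <- precision_recall_dice(tab)
  ap <- average_precision(predictions, truths, iou_threshold)
  pq <- panoptic_quality(predictions, truths, iou_threshold)
  structure(c(prd, list(ap = ap$ap), pq,
              list(curve = ap$curve, match_table = tab,
                   iou_threshold = iou_threshold)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Instance segmentation metrics (IoU threshold %.2f)\n",
              x$iou_threshold))
  cat(sprintf("  TP %d  FP %d  FN %d\n", x$match_table$tp,
              x$match_table$fp_count, x$match_table$fn_count))
  for (nm in c("precision", "recall", "dice", "ap", "dq", "sq", "pq")) {
    cat(sprintf("  %-9s %.4f\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Write a metrics report to JSON and TSV
#'
#' @param report A [evaluate_detections()] result.
#' @param json_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_metrics_report <- function(report, json_path = NULL, tsv_path = NULL) {
  vals <- report[c("precision", "recall", "dice", "ap", "dq", "sq", "pq")]
  if (!is.null(json_path)) {
    jsonlite::write_json(vals, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(metric = names(vals), value = unlist(vals))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report)
}

# ---- internal ---------------------------------------------------------------

safe_div <- function(num, den) if (den == 0) 0 else num / den

normalize_predictions <- function(predictions) {
  n <- length(predictions)
  lapply(seq_len(n), function(i) {
    p <- predictions[[i]]
    if (is.list(p) && !is.null(p$mask)) {
      list(mask = p$mask, score = p$score %||% 1)
    } else {
      # bare mask: score by reverse list order so earlier entries rank higher
      list(mask = p, score = 1 - (i - 1) / max(1L, n) * 1e-6)
    }
  })
}
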