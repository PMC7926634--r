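# Bounding-box detection evaluation: IoU, greedy confidence-ordered matching
# at a fixed IoU threshold (darknet-style mAP@0.5), per-class AP with
# all-point PR interpolation, F1 and per-sequence detection coverage.

#' Intersection over union of two boxes
#'
#' Continuous (half-open interval) convention: areas are
#' `(x_max - x_min) * (y_max - y_min)`; disjoint boxes give 0.
#'
#' @param a,b one-row box data.frames (see [bounding_box()]).
#' @return IoU in \[0, 1\].
#' @export
iou <- function(a, b) {
  ix <- min(a$x_max, b$x_max) - max(a$x_min, b$x_min)
  iy <- min(a$y_max, b$y_max) - max(a$y_min, b$y_min)
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  ua <- (a$x_max - a$x_min) * (a$y_max - a$y_min) +
        (b$x_max - b$x_min) * (b$y_max - b$y_min) - inter
  inter / ua
}

iou_matrix <- function(preds, truths) {
  outer(seq_len(nrow(preds)), seq_len(nrow(truths)),
        Vectorize(function(i, j) iou(preds[i, ], truths[j, ])))
}

# Greedy matcher used by both match_detections and average_precision.
# Predictions are taken in decreasing confidence (ties: input order); each
# claims the not-yet-matched truth of highest IoU if that IoU >= threshold.
# `frame` columns, when present, restrict matches to the same frame.
greedy_match <- function(preds, truths, iou_threshold) {
  np <- nrow(preds); nt <- nrow(truths)
  is_tp <- logical(np); tp_iou <- rep(NA_real_, np)
  matched_truth <- integer(np)
  if (np && nt) {
    ord <- order(-preds$confidence)
    taken <- logical(nt)
    pf <- if ("frame" %in% names(preds)) preds$frame else rep(1L, np)
    tf <- if ("frame" %in% names(truths)) truths$frame else rep(1L, nt)
    for (i in ord) {
      cand <- which(!taken & tf == pf[i])
      if (!length(cand)) next
      ious <- vapply(cand, function(j) iou(preds[i, ], truths[j, ]),
                     numeric(1))
      best <- which.max(ious)
      if (ious[best] >= iou_threshold) {
        taken[cand[best]] <- TRUE
        is_tp[i] <- TRUE
        tp_iou[i] <- ious[best]
        matched_truth[i] <- cand[best]
      }
    }
  }
  list(is_tp = is_tp, tp_iou = tp_iou, matched_truth = matched_truth)
}

#' Match predicted against ground-truth boxes
#'
#' Per class, predictions are sorted by descending confidence and each claims
#' the unmatched ground-truth box of highest IoU provided it reaches
#' `iou_threshold`; remaining predictions are false positives and remaining
#' truths false negatives.  If both inputs carry a `frame` column, matching
#' is restricted to boxes of the same frame.
#'
#' @param preds box data.frame with confidences (optionally a `frame` column).
#' @param truths box data.frame of ground truth.
#' @param iou_threshold matching threshold (default 0.5).
#' @return An object of class `match_result`: list with `per_class` counts
#'   (tp/fp/fn and mean IoU over matched pairs) and aggregate `tp`, `fp`,
#'   `fn`.
#' @export
match_detections <- function(preds, truths, iou_threshold = 0.5) {
  classes <- sort(unique(c(preds$label, truths$label)))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    p <- preds[preds$label == cl, , drop = FALSE]
    t <- truths[truths$label == cl, , drop = FALSE]
    m <- greedy_match(p, t, iou_threshold)
    data.frame(label = cl, tp = sum(m$is_tp), fp = sum(!m$is_tp),
               fn = nrow(t) - sum(m$is_tp),
               mean_iou = if (any(m$is_tp)) mean(m$tp_iou[m$is_tp]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_class)) per_class <- data.frame(
    label = character(), tp = integer(), fp = integer(), fn = integer(),
    mean_iou = numeric(), stringsAsFactors = FALSE)
  structure(list(per_class = per_class,
                 tp = sum(per_class$tp), fp = sum(per_class$fp),
                 fn = sum(per_class$fn), iou_threshold = iou_threshold),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result @IoU>=%g: TP=%d FP=%d FN=%d>\n",
              x$iou_threshold, x$tp, x$fp, x$fn))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Average precision for one class
#'
#' Area under the monotonized precision-recall curve obtained by sweeping the
#' confidence-sorted prediction list (all-point interpolation, the
#' convention of darknet's mAP@0.5 evaluator).  Ties in confidence keep
#' input order.
#'
#' @inheritParams match_detections
#' @param class class label evaluated.
#' @return AP in \[0, 1\], or `NA` if the class has no ground truth
#'   (such classes are excluded from [mean_average_precision()]).
#' @export
average_precision <- function(preds, truths, class, iou_threshold = 0.5) {
  p <- preds[preds$label == class, , drop = FALSE]
  t <- truths[truths$label == class, , drop = FALSE]
  if (!nrow(t)) return(NA_real_)
  if (!nrow(p)) return(0)
  m <- greedy_match(p, t, iou_threshold)
  ord <- order(-p$confidence)
  tp_cum <- cumsum(m$is_tp[ord])
  fp_cum <- cumsum(!m$is_tp[ord])
  recall <- tp_cum / nrow(t)
  precision <- tp_cum / (tp_cum + fp_cum)
  # monotonize precision from the right, integrate over recall increments
  prec_mono <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * prec_mono)
}

#' Mean average precision over classes present in ground truth
#'
#' @inheritParams match_detections
#' @return mAP in \[0, 1\].
#' @export
mean_average_precision <- function(preds, truths, iou_threshold = 0.5) {
  classes <- unique(truths$label)
  aps <- vapply(classes, function(cl)
    average_precision(preds, truths, cl, iou_threshold), numeric(1))
  mean(aps, na.rm = TRUE)
}

#' F1 score of a match result
#'
#' Harmonic mean of precision and recall; 0 when precision + recall is 0,
#' `NA` when there are neither predictions nor ground truths.
#'
#' @param match a [match_detections()] result (or any list with `tp`, `fp`,
#'   `fn` counts).
#' @return F1 in \[0, 1\] or `NA`.
#' @export
f1_score <- function(match) {
  tp <- match$tp; fp <- match$fp; fn <- match$fn
  if (tp + fp + fn == 0) return(NA_real_)
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' Detection coverage of a class over a sequence
#'
#' Share of frames containing at least one box of the class, in percent
#' (the per-patient "coverage of successful detections" accounting).
#'
#' @param track a [roi_track()].
#' @param label class label.
#' @param n_frames number of frames (defaults to the track length).
#' @return Percentage in \[0, 100\].
#' @export
detection_coverage <- function(track, label, n_frames = length(track)) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  hit <- vapply(seq_len(n_frames), function(i) {
    i <= length(track) && any(track[[i]]$label == label)
  }, logical(1))
  100 * mean(hit)
}

#' Full detection metrics for a predicted track against a truth track
#'
#' Pools boxes over frames (matching restricted within frames) and reports
#' per-class AP and mean IoU, mAP over classes present in the ground truth,
#' and the aggregate F1.
#'
#' @param pred_track,truth_track [roi_track()]s of equal length.
#' @param iou_threshold matching threshold (default 0.5).
#' @return List with `per_class` data.frame, `map`, `f1` and the aggregate
#'   `match` result.
#' @export
detection_metrics <- function(pred_track, truth_track, iou_threshold = 0.5) {
  stopifnot(length(pred_track) == length(truth_track))
  pool <- function(track) {
    do.call(rbind, lapply(seq_along(track), function(i) {
      b <- track[[i]]
      if (nrow(b)) b$frame <- i
      b
    }))
  }
  preds <- pool(pred_track); truths <- pool(truth_track)
  if (is.null(preds)) preds <- cbind(empty_boxes(), frame = integer())
  if (is.null(truths)) truths <- cbind(empty_boxes(), frame = integer())
  m <- match_detections(preds, truths, iou_threshold)
  classes <- unique(truths$label)
  ap <- vapply(classes, function(cl)
    average_precision(preds, truths, cl, iou_threshold), numeric(1))
  per_class <- merge(m$per_class,
                     data.frame(label = classes, ap = ap,
                                stringsAsFactors = FALSE),
                     by = "label", all.x = TRUE)
  list(per_class = per_class,
       map = mean(ap, na.rm = TRUE),
       f1 = f1_score(m),
       match = m)
}
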