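#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are `c(xmin, ymin, xmax, ymax)` with `min <= max` per axis.
#' Disjoint boxes give 0; a pair of zero-area boxes gives 0 with a warning.
#'
#' @param box_a,box_b Numeric length-4 boxes.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(box_a, box_b) {
  stopifnot(length(box_a) == 4, length(box_b) == 4)
  if (box_a[1] > box_a[3] || box_a[2] > box_a[4] ||
      box_b[1] > box_b[3] || box_b[2] > box_b[4])
    stop("invalid box: min exceeds max", call. = FALSE)
  area <- function(b) (b[3] - b[1]) * (b[4] - b[2])
  iw <- max(0, min(box_a[3], box_b[3]) - max(box_a[1], box_b[1]))
  ih <- max(0, min(box_a[4], box_b[4]) - max(box_a[2], box_b[2]))
  inter <- iw * ih
  uni <- area(box_a) + area(box_b) - inter
  if (uni == 0) {
    warning("degenerate zero-area boxes; IoU set to 0", call. = FALSE)
    return(0)
  }
  inter / uni
}

#' Precision and recall from match counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` at a stated IoU
#' threshold. Undefined ratios (zero denominators) are reported as `NA` with
#' the corresponding `*_defined` flag, never silently as 0.
#'
#' @param tp,fp,fn Non-negative integer counts.
#' @return List `precision`, `recall`, `precision_defined`, `recall_defined`.
#' @export
precision_recall <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision_defined = tp + fp > 0,
       recall_defined = tp + fn > 0)
}

# Greedy score-ordered matching for one class; returns per-detection TP flags.
.match_detections <- function(det_boxes, det_scores, gt_boxes, iou_threshold) {
  ord <- order(det_scores, decreasing = TRUE)
  matched <- rep(FALSE, length(gt_boxes))
  tp <- logical(length(ord))
  for (i in seq_along(ord)) {
    db <- det_boxes[[ord[i]]]
    best_iou <- 0; best_j <- 0
    for (j in seq_along(gt_boxes)) {
      if (matched[j]) next
      ov <- iou(db, gt_boxes[[j]])
      if (ov > best_iou) { best_iou <- ov; best_j <- j }
    }
    if (best_j > 0 && best_iou >= iou_threshold) {
      tp[i] <- TRUE
      matched[best_j] <- TRUE
    }
  }
  tp
}

# All-points (continuous) interpolated area under the precision-recall curve.
.average_precision <- function(tp_flags, n_gt) {
  if (length(tp_flags) == 0) return(0)
  cum_tp <- cumsum(tp_flags)
  cum_fp <- cumsum(!tp_flags)
  recall <- cum_tp / n_gt
  precision <- cum_tp / (cum_tp + cum_fp)
  # precision envelope, integrated over recall increments
  r <- c(0, recall)
  p <- c(1, precision)
  for (i in rev(seq_len(length(p) - 1))) p[i] <- max(p[i], p[i + 1])
  sum(diff(r) * p[-1])
}

#' Mean average precision at IoU 0.50
#'
#' Score-ordered greedy matching (each ground-truth box matched at most
#' once, positive if IoU >= the threshold), per-class average precision as
#' the area under the all-points-interpolated precision-recall curve, and
#' the unweighted mean over classes. Classes with detections but no ground
#' truth are excluded with a warning (their AP is undefined).
#'
#' @param detections Data.frame with columns `class`, `score`, and either a
#'   list-column `box` or columns `xmin, ymin, xmax, ymax`.
#' @param ground_truth Data.frame with `class` and the same box encoding.
#' @param iou_threshold Matching threshold (default 0.5).
#' @return List `map` (the mAP@50), `per_class` (named APs), `skipped_classes`.
#' @export
map50 <- function(detections, ground_truth, iou_threshold = 0.5) {
  get_boxes <- function(df) {
    if ("box" %in% names(df)) df$box
    else lapply(seq_len(nrow(df)), function(i)
      as.numeric(df[i, c("xmin", "ymin", "xmax", "ymax")]))
  }
  gt_classes <- unique(as.character(ground_truth$class))
  det_classes <- unique(as.character(detections$class))
  skipped <- setdiff(det_classes, gt_classes)
  if (length(skipped))
    warning("no ground truth for class(es): ", paste(skipped, collapse = ", "),
            "; excluded from mAP", call. = FALSE)
  if (length(gt_classes) == 0) stop("empty ground truth", call. = FALSE)
  ap <- vapply(gt_classes, function(cl) {
    gt_b <- get_boxes(ground_truth[as.character(ground_truth$class) == cl, , drop = FALSE])
    sel <- as.character(detections$class) == cl
    if (!any(sel)) return(0)
    det <- detections[sel, , drop = FALSE]
    # .match_detections returns flags already in score-descending order
    tp <- .match_detections(get_boxes(det), det$score, gt_b, iou_threshold)
    .average_precision(tp, length(gt_b))
  }, numeric(1))
  list(map = mean(ap), per_class = ap, skipped_classes = skipped)
}
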