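# Detection-accuracy metrics: precision, recall, AP as the area under the
# P(R) curve, mAP at IoU 0.5 and averaged over 0.5:0.95, the F1 harmonic
# mean, and class-confusion matrices with a background row/column.
#
# Detections and ground truths are plain data frames:
#   detections: image, class, score, x1, y1, x2, y2
#   truths:     image, class, x1, y1, x2, y2
# Matching is greedy in descending score, one-to-one per ground-truth box,
# requiring same class and IoU >= threshold; ties break to the higher IoU
# and then the lower detection index.

#' Pairwise IoU matrix between two sets of corner-form boxes
#' @param a n x 4 matrix, `b` m x 4 matrix.
#' @return n x m matrix of IoU values.
#' @export
box_iou_matrix <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  n <- nrow(a); m <- nrow(b)
  ix1 <- outer(a[, 1], b[, 1], pmax)
  iy1 <- outer(a[, 2], b[, 2], pmax)
  ix2 <- outer(a[, 3], b[, 3], pmin)
  iy2 <- outer(a[, 4], b[, 4], pmin)
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  aa <- pmax(a[, 3] - a[, 1], 0) * pmax(a[, 4] - a[, 2], 0)
  ab <- pmax(b[, 3] - b[, 1], 0) * pmax(b[, 4] - b[, 2], 0)
  un <- outer(aa, ab, "+") - inter
  out <- inter / pmax(un, 1e-12)
  out[un <= 0] <- 0
  matrix(out, n, m)
}

det_box_cols <- c("x1", "y1", "x2", "y2")

# greedy one-to-one matching of one class on one image;
# returns logical TP flags aligned with det order (already score-sorted)
greedy_match_flags <- function(det_boxes, gt_boxes, iou_thr) {
  nd <- nrow(det_boxes)
  ng <- nrow(gt_boxes)
  tp <- logical(nd)
  if (nd == 0L || ng == 0L) return(tp)
  iom <- box_iou_matrix(det_boxes, gt_boxes)
  used <- logical(ng)
  for (i in seq_len(nd)) {
    ious <- iom[i, ]
    ious[used] <- -1
    j <- which.max(ious)
    if (ious[j] >= iou_thr) {
      tp[i] <- TRUE
      used[j] <- TRUE
    }
  }
  tp
}

#' Average precision from a ranked TP/FP list
#'
#' Computes AP as the area under the precision-recall curve of a ranked
#' detection list.
#'
#' @param tp logical vector in rank order (highest score first).
#' @param n_gt number of ground-truth boxes.
#' @param interpolation `"coco101"` (101-point interpolation) or
#'   `"continuous"` (all-point interpolation of the precision envelope).
#' @export
average_precision <- function(tp, n_gt, interpolation = c("coco101", "continuous")) {
  interpolation <- match.arg(interpolation)
  if (n_gt == 0L) return(NA_real_)
  if (length(tp) == 0L) return(0)
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  rec <- ctp / n_gt
  prec <- ctp / (ctp + cfp)
  # precision envelope: best precision at recall >= r
  env <- rev(cummax(rev(prec)))
  if (interpolation == "coco101") {
    grid <- seq(0, 1, by = 0.01)
    pr <- vapply(grid, function(r) {
      k <- which(rec >= r - 1e-12)
      if (length(k) == 0L) 0 else env[k[1]]
    }, numeric(1))
    mean(pr)
  } else {
    r <- c(0, rec)
    p <- c(env[1], env)
    sum(diff(r) * p[-1])
  }
}

# sort detections by score desc, stable in original order
sort_dets <- function(dets) {
  dets[order(-dets$score, seq_len(nrow(dets))), , drop = FALSE]
}

#' Evaluate detections against ground truth
#'
#' Precision and recall are computed at IoU 0.5 over all supplied
#' detections; AP per class is the area under P(R); mAP50 and mAP50:95 are
#' class means (over classes that appear in the ground truth); F1 is the
#' harmonic mean `2PR/(P+R)`.
#'
#' @param dets data frame with columns image, class, score, x1, y1, x2, y2.
#' @param gts data frame with columns image, class, x1, y1, x2, y2.
#' @param iou_thresholds thresholds for the mAP average (default 0.5:0.95).
#' @param interpolation AP integration rule, see [average_precision()].
#' @return list with precision, recall, f1, map50, map5095, per_class
#'   (AP50 and AP50:95 per class), and counts.
#' @export
evaluate_detections <- function(dets, gts,
                                iou_thresholds = seq(0.5, 0.95, by = 0.05),
                                interpolation = c("coco101", "continuous")) {
  interpolation <- match.arg(interpolation)
  classes <- sort(unique(gts$class))
  n_gt_total <- nrow(gts)
  dets <- sort_dets(dets)
  # per class x threshold AP, plus dataset-level TP at 0.5
  ap <- matrix(NA_real_, length(classes), length(iou_thresholds),
               dimnames = list(as.character(classes), NULL))
  tp50_total <- 0L
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    dc <- dets[dets$class == cl, , drop = FALSE]
    gc <- gts[gts$class == cl, , drop = FALSE]
    for (ti in seq_along(iou_thresholds)) {
      thr <- iou_thresholds[ti]
      tp <- logical(nrow(dc))
      for (img in unique(c(dc$image, gc$image))) {
        di <- which(dc$image == img)
        gi <- which(gc$image == img)
        if (length(di) == 0L) next
        tp[di] <- greedy_match_flags(
          as.matrix(dc[di, det_box_cols, drop = FALSE]),
          as.matrix(gc[gi, det_box_cols, drop = FALSE]), thr)
      }
      ap[ci, ti] <- average_precision(tp, nrow(gc), interpolation)
      if (abs(thr - 0.5) < 1e-9) tp50_total <- tp50_total + sum(tp)
    }
  }
  n_det <- nrow(dets)
  fp50 <- n_det - tp50_total
  fn50 <- n_gt_total - tp50_total
  precision <- if (n_det > 0L) tp50_total / n_det else if (n_gt_total == 0L) 1 else 0
  recall <- if (n_gt_total > 0L) tp50_total / n_gt_total else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) 2 * precision * recall / (precision + recall) else 0
  i50 <- which(abs(iou_thresholds - 0.5) < 1e-9)
  per_class <- data.frame(
    class = classes,
    ap50 = if (length(i50)) ap[, i50[1]] else NA_real_,
    ap = rowMeans(ap),
    row.names = NULL)
  list(precision = precision, recall = recall, f1 = f1,
       map50 = if (length(i50)) mean(ap[, i50[1]]) else NA_real_,
       map5095 = mean(ap),
       per_class = per_class,
       tp = tp50_total, fp = fp50, fn = fn50)
}

#' Detection confusion matrix with background row and column
#'
#' Rows are true classes (last row = background, i.e. false detections);
#' columns are predicted classes (last column = background, i.e. missed
#' ground truths). Matching is greedy in descending score, class-agnostic,
#' at a fixed IoU and confidence threshold.
#'
#' @param n_classes number of object classes (class ids 0..n_classes-1).
#' @param normalize row-normalize to proportions.
#' @export
confusion_matrix_det <- function(dets, gts, n_classes, iou_thr = 0.5,
                                 conf_thr = 0.25, normalize = FALSE) {
  labs <- c(as.character(seq_len(n_classes) - 1L), "background")
  cm <- matrix(0, n_classes + 1L, n_classes + 1L, dimnames = list(
    truth = labs, predicted = labs))
  dets <- dets[dets$score >= conf_thr, , drop = FALSE]
  dets <- sort_dets(dets)
  bg <- n_classes + 1L
  for (img in unique(c(dets$image, gts$image))) {
    dc <- dets[dets$image == img, , drop = FALSE]
    gc <- gts[gts$image == img, , drop = FALSE]
    used <- logical(nrow(gc))
    if (nrow(dc) > 0L && nrow(gc) > 0L) {
      iom <- box_iou_matrix(as.matrix(dc[, det_box_cols]),
                            as.matrix(gc[, det_box_cols]))
      for (i in seq_len(nrow(dc))) {
        ious <- iom[i, ]
        ious[used] <- -1
        j <- which.max(ious)
        if (ious[j] >= iou_thr) {
          used[j] <- TRUE
          cm[gc$class[j] + 1L, dc$class[i] + 1L] <- cm[gc$class[j] + 1L, dc$class[i] + 1L] + 1
        } else {
          cm[bg, dc$class[i] + 1L] <- cm[bg, dc$class[i] + 1L] + 1
        }
      }
    } else if (nrow(dc) > 0L) {
      for (i in seq_len(nrow(dc)))
        cm[bg, dc$class[i] + 1L] <- cm[bg, dc$class[i] + 1L] + 1
    }
    if (any(!used) && nrow(gc) > 0L) {
      for (j in which(!used))
        cm[gc$class[j] + 1L, bg] <- cm[gc$class[j] + 1L, bg] + 1
    }
  }
  if (normalize) {
    rs <- rowSums(cm)
    cm <- sweep(cm, 1L, pmax(rs, 1), "/")
  }
  cm
}

#' F1 score, the harmonic mean of precision and recall
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}
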