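# COCO-style mean average precision with 101-point interpolated precision,
# greedy confidence-ordered matching and per-class non-maximum suppression.

# IoU between one corner-form box and a matrix of corner-form boxes.
iou_vec <- function(b, m) {
  if (nrow(m) == 0) return(numeric(0))
  iw <- pmax(0, pmin(b[3], m[, 3]) - pmax(b[1], m[, 1]))
  ih <- pmax(0, pmin(b[4], m[, 4]) - pmax(b[2], m[, 2]))
  inter <- iw * ih
  ua <- (b[3] - b[1]) * (b[4] - b[2]) +
    (m[, 3] - m[, 1]) * (m[, 4] - m[, 2]) - inter
  inter / ua
}

records_to_corners <- function(df) {
  cbind(df$cx - df$w / 2, df$cy - df$h / 2, df$cx + df$w / 2, df$cy + df$h / 2)
}

#' Greedy per-class non-maximum suppression
#'
#' Detections are visited in decreasing confidence; a detection is dropped
#' when it overlaps an already-kept detection of the same class above
#' `nms_iou`.
#'
#' @param det Data frame with columns `class_id, cx, cy, w, h, confidence`.
#' @param nms_iou Suppression IoU threshold (default 0.7).
#' @return The kept subset of `det`.
#' @export
nms <- function(det, nms_iou = 0.7) {
  if (nrow(det) == 0) return(det)
  det <- det[order(-det$confidence), , drop = FALSE]
  corners <- records_to_corners(det)
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    prev <- which(keep & det$class_id == det$class_id[i])
    if (length(prev) == 0 ||
        all(iou_vec(corners[i, ], corners[prev, , drop = FALSE]) <= nms_iou))
      keep[i] <- TRUE
  }
  det[keep, , drop = FALSE]
}

# 101-point interpolated AP from unsorted (conf, tp) pairs and GT count.
ap_101 <- function(conf, tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(conf) == 0) return(0)
  o <- order(-conf)
  tp <- tp[o]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / (cum_tp + cum_fp)
  # precision envelope, then mean over 101 recall points
  env <- rev(cummax(rev(precision)))
  rp <- seq(0, 1, by = 0.01)
  idx <- findInterval(rp, recall, left.open = TRUE) + 1
  p <- ifelse(idx <= length(env), env[idx], 0)
  mean(p)
}

#' Evaluate detections with mean average precision
#'
#' Matches detections to ground truth greedily in decreasing confidence
#' (one match per ground-truth box, best unmatched IoU wins) at each IoU
#' threshold, computes per-class AP via 101-point interpolated precision,
#' and averages: `mAP50` at threshold 0.5 and `mAP50-95` over thresholds
#' 0.50 to 0.95 in steps of 0.05.
#'
#' @param detections Data frame with columns
#'   `image_id, class_id, cx, cy, w, h, confidence`.
#' @param ground_truth Data frame with columns
#'   `image_id, class_id, cx, cy, w, h`.
#' @param num_classes Size of the class vocabulary.
#' @param iou_thresholds Vector of IoU thresholds.
#' @return An `eval_result` with `ap` (class x threshold matrix),
#'   `per_class_ap50`, `map50`, `map50_95` and the PR curves at 0.5.
#' @export
evaluate_map <- function(detections, ground_truth, num_classes = 4L,
                         iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (nrow(detections) > 0 &&
      any(!detections$class_id %in% 0:(num_classes - 1)))
    stop("evaluate_map: detection class id outside vocabulary")
  if (nrow(ground_truth) > 0 &&
      any(!ground_truth$class_id %in% 0:(num_classes - 1)))
    stop("evaluate_map: ground-truth class id outside vocabulary")
  ap <- matrix(NA_real_, num_classes, length(iou_thresholds),
               dimnames = list(class = NULL, thr = iou_thresholds))
  pr_curves <- vector("list", num_classes)
  for (cls in 0:(num_classes - 1)) {
    gt_c <- ground_truth[ground_truth$class_id == cls, , drop = FALSE]
    det_c <- detections[detections$class_id == cls, , drop = FALSE]
    det_c <- det_c[order(-det_c$confidence), , drop = FALSE]
    n_gt <- nrow(gt_c)
    for (ti in seq_along(iou_thresholds)) {
      thr <- iou_thresholds[ti]
      matched <- logical(n_gt)
      tp <- logical(nrow(det_c))
      if (nrow(det_c) > 0) {
        dc <- records_to_corners(det_c)
        gc <- records_to_corners(gt_c)
        for (i in seq_len(nrow(det_c))) {
          cand <- which(!matched & gt_c$image_id == det_c$image_id[i])
          if (length(cand) == 0) next
          ious <- iou_vec(dc[i, ], gc[cand, , drop = FALSE])
          j <- which.max(ious)
          if (ious[j] >= thr) {
            matched[cand[j]] <- TRUE
            tp[i] <- TRUE
          }
        }
      }
      ap[cls + 1, ti] <- ap_101(det_c$confidence, tp, n_gt)
      if (thr == 0.5 && n_gt > 0 && nrow(det_c) > 0) {
        ct <- cumsum(tp); cf <- cumsum(!tp)
        pr_curves[[cls + 1]] <- list(recall = ct / n_gt,
                                     precision = ct / (ct + cf))
      }
    }
  }
  ap50 <- ap[, 1]
  structure(list(ap = ap,
                 per_class_ap50 = ap50,
                 map50 = mean(ap50, na.rm = TRUE),
                 map50_95 = mean(rowMeans(ap), na.rm = TRUE),
                 pr_curves = pr_curves),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("mAP50 = %.4f, mAP50-95 = %.4f\n", x$map50, x$map50_95))
  cat("per-class AP50:", sprintf("%.3f", x$per_class_ap50), "\n")
  invisible(x)
}
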