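#' Fusion configuration for the two-detector ensemble
#'
#' The one-stage and two-stage detectors are run on the same image and their
#' detections fused. Under `weighted_box_fusion`, same-class detections with
#' pairwise IoU at or above `match_iou` are merged: coordinates are averaged
#' with weights `model_weight * score`, scores are the model-weighted mean,
#' and unmatched detections pass through scaled by their model's weight.
#' Under `nms_union` the two lists are concatenated and the merge step acts
#' like class-wise NMS with score-weighted averaging, unmatched detections
#' passing through unscaled.
#'
#' @param match_iou IoU at which two detections are considered the same
#'   object (default 0.55).
#' @param weights non-negative model weights `(one-stage, two-stage)`
#'   summing to 1.
#' @param strategy `"weighted_box_fusion"` or `"nms_union"`.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(match_iou = 0.55, weights = c(0.5, 0.5),
                          strategy = c("weighted_box_fusion", "nms_union")) {
  strategy <- match.arg(strategy)
  if (match_iou <= 0 || match_iou >= 1) abort("match_iou must be in (0, 1)")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    abort("weights must be non-negative and sum to 1")
  }
  structure(list(match_iou = match_iou, weights = weights, strategy = strategy),
            class = "fusion_config")
}

#' Fuse detections from the two detectors
#'
#' @param dets_a,dets_b detection tibbles from the same image and class
#'   vocabulary (conventionally the one-stage and two-stage detectors).
#' @param config a [fusion_config()].
#' @return A detection tibble with `source = "ensemble"`, sorted by
#'   descending score. Fused boxes never leave the union of the input
#'   extents and the output never exceeds `nrow(dets_a) + nrow(dets_b)`.
#' @export
fuse_detections <- function(dets_a, dets_b, config = fusion_config()) {
  wa <- config$weights[1]; wb <- config$weights[2]
  a <- dets_a; b <- dets_b
  if (nrow(a)) a$model_w <- wa
  if (nrow(b)) b$model_w <- wb
  all <- dplyr::bind_rows(a, b)
  if (!nrow(all)) return(empty_detections())
  # deterministic order: score, then coordinates as tie-break
  all <- all[order(-all$score, all$x1, all$y1, all$x2, all$y2), ]
  used <- rep(FALSE, nrow(all))
  out <- list()
  m <- iou_matrix_cpp(as.matrix(all[, c("x1", "y1", "x2", "y2")]),
                      as.matrix(all[, c("x1", "y1", "x2", "y2")]))
  for (i in seq_len(nrow(all))) {
    if (used[i]) next
    grp <- which(!used & all$class_id == all$class_id[i] & m[i, ] >= config$match_iou)
    grp <- union(i, grp)
    used[grp] <- TRUE
    g <- all[grp, ]
    cw <- g$model_w * g$score
    if (sum(cw) <= 0) cw <- rep(1, nrow(g))
    fused_score <- if (length(unique(g$source)) > 1) {
      # matched across models: model-weighted mean score
      sum(vapply(split(g$score * g$model_w, g$source), sum, numeric(1))) /
        sum(vapply(split(g$model_w, g$source), max, numeric(1)))
    } else if (config$strategy == "weighted_box_fusion") {
      max(g$score) * g$model_w[1]
    } else {
      max(g$score)
    }
    out[[length(out) + 1]] <- tibble(
      x1 = sum(g$x1 * cw) / sum(cw), y1 = sum(g$y1 * cw) / sum(cw),
      x2 = sum(g$x2 * cw) / sum(cw), y2 = sum(g$y2 * cw) / sum(cw),
      class_id = g$class_id[1], class_name = g$class_name[1],
      score = min(fused_score, 1), source = "ensemble"
    )
  }
  res <- dplyr::bind_rows(out)
  res[order(-res$score, res$x1, res$y1), ]
}

#' Run both detectors and fuse
#'
#' @param yolo a `pv_inc_yolo`; `rcnn` a `pv_cluster_rcnn`.
#' @param rcnn the two-stage model.
#' @param image `H x W x 3` 8-bit array.
#' @param config a [fusion_config()].
#' @param conf_thresh per-model confidence floors `(yolo, rcnn)`.
#' @param class_names optional labels.
#' @return A fused detection tibble.
#' @export
ensemble_detect <- function(yolo, rcnn, image, config = fusion_config(),
                            conf_thresh = c(0.25, 0.5), class_names = NULL) {
  da <- inc_yolo_detect(yolo, image, conf_thresh[1], class_names = class_names)
  db <- cluster_rcnn_detect(rcnn, image, conf_thresh[2], class_names = class_names)
  fuse_detections(da, db, config)
}
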