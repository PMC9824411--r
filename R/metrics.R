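#' Match detections to ground truth on one image
#'
#' Detections are processed in order of descending score; each one claims the
#' unmatched ground-truth box of highest IoU provided that IoU reaches
#' `iou_thresh` (a true positive), otherwise it is a false positive.
#' Ground-truth boxes left unclaimed are false negatives. There is no
#' true-negative count for detection (there are no negative boxes), so `tn`
#' is fixed at 0.
#'
#' @param dets detection tibble for one image and one class (needs `score`).
#' @param gts ground-truth box tibble for the same image and class.
#' @param iou_thresh minimum IoU for a match (default 0.5).
#' @return A list with `counts` (tibble `tp`, `fp`, `fn`, `tn`) and `matches`
#'   (per-detection tibble with `score`, `matched_gt`, `tp`).
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  nd <- nrow(dets); ng <- nrow(gts)
  matches <- tibble(score = numeric(nd), matched_gt = NA_integer_, tp = logical(nd))
  if (nd > 0) {
    ord <- order(-dets$score, seq_len(nd))
    m <- if (ng > 0) {
      iou_matrix_cpp(as.matrix(dets[, c("x1", "y1", "x2", "y2")]),
                     as.matrix(gts[, c("x1", "y1", "x2", "y2")]))
    } else matrix(0, nd, 0)
    taken <- rep(FALSE, ng)
    matches$score <- dets$score
    for (i in ord) {
      if (ng == 0) break
      free <- which(!taken)
      if (!length(free)) next
      j <- free[which.max(m[i, free])]
      if (m[i, j] >= iou_thresh) {
        taken[j] <- TRUE
        matches$matched_gt[i] <- j
        matches$tp[i] <- TRUE
      }
    }
  }
  tp <- sum(matches$tp)
  list(
    counts = tibble(tp = tp, fp = nd - tp, fn = ng - tp, tn = 0L),
    matches = matches
  )
}

#' Precision and recall from confusion counts
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`. When the
#' denominator is empty (no detections, or no positive samples) the
#' convention is to return 1 and set the `degenerate` attribute, so that a
#' detector that makes no claims on an empty class is not penalised.
#'
#' @param counts a tibble or list with `tp`, `fp`, `fn`.
#' @return A numeric scalar in `[0, 1]`, with attribute `degenerate = TRUE`
#'   when the empty-denominator convention fired.
#' @export
precision <- function(counts) {
  den <- counts$tp + counts$fp
  if (den == 0) return(structure(1, degenerate = TRUE))
  counts$tp / den
}

#' @rdname precision
#' @export
recall <- function(counts) {
  den <- counts$tp + counts$fn
  if (den == 0) return(structure(1, degenerate = TRUE))
  counts$tp / den
}

#' Average precision over a ranked detection sweep
#'
#' Detections pooled over the test set are ranked by descending score; the
#' precision-recall curve is swept and AP is the sum of precision times
#' recall increment over the sweep (all-point, uninterpolated — the area
#' under the discrete PR curve, with the recall increments summing to 1 when
#' every positive is recovered). The classical 11-point interpolation is
#' available via `interpolation = "11point"`.
#'
#' @param scores detection confidences.
#' @param is_tp logical, whether each detection matched a ground truth.
#' @param n_gt total number of ground-truth boxes for the class.
#' @param interpolation `"all"` (default) or `"11point"`.
#' @return AP in `[0, 1]`; `NA` (with a warning) when `n_gt` is 0.
#' @export
average_precision <- function(scores, is_tp, n_gt, interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  if (n_gt == 0) {
    warn("AP undefined for a class with no ground-truth boxes")
    return(NA_real_)
  }
  if (length(scores) == 0 || !any(is_tp)) return(0)
  ord <- order(-scores, seq_along(scores))
  tp_c <- cumsum(is_tp[ord])
  fp_c <- cumsum(!is_tp[ord])
  prec <- tp_c / (tp_c + fp_c)
  rec <- tp_c / n_gt
  if (interpolation == "11point") {
    return(mean(vapply(seq(0, 1, 0.1), function(r) {
      p <- prec[rec >= r - 1e-12]
      if (length(p)) max(p) else 0
    }, numeric(1))))
  }
  dr <- diff(c(0, rec))
  sum(prec * dr)
}

#' Mean average precision
#'
#' The arithmetic mean of per-class AP values; classes whose AP is undefined
#' (no ground truth) are excluded.
#'
#' @param per_class_ap named numeric vector of per-class APs.
#' @return mAP in `[0, 1]`.
#' @export
mean_ap <- function(per_class_ap) {
  ok <- !is.na(per_class_ap)
  if (!any(ok)) abort("no class has a defined AP")
  mean(per_class_ap[ok])
}

#' Evaluate detections against a ground-truth manifest
#'
#' Pools detections over all images, matches them per class at `iou_thresh`
#' ([match_detections()]), computes per-class AP ([average_precision()]) and
#' mAP ([mean_ap()]).
#'
#' @param detections tibble of detections with `image_id`, box columns,
#'   `class_id`, `class_name`, `score`.
#' @param gt_manifest manifest tibble with ground-truth `boxes`.
#' @param iou_thresh match threshold (default 0.5).
#' @param interpolation passed to [average_precision()].
#' @return An object of class `pv_eval`: list with `per_class` (tibble of
#'   `class_name`, `ap`, `tp`, `fp`, `fn`, `n_gt`), `map`, `iou_thresh` and
#'   the per-detection `sweep` table (for PR curves).
#' @export
evaluate_detections <- function(detections, gt_manifest, iou_thresh = 0.5,
                                interpolation = "all") {
  gt_all <- purrr::map2_dfr(gt_manifest$image_id, gt_manifest$boxes,
                            ~ dplyr::mutate(.y, image_id = .x))
  classes <- sort(unique(c(gt_all$class_name, detections$class_name)))
  per_class <- purrr::map_dfr(classes, function(cl) {
    sweep <- purrr::map_dfr(gt_manifest$image_id, function(id) {
      d <- detections[detections$image_id == id & detections$class_name == cl, ]
      g <- gt_all[gt_all$image_id == id & gt_all$class_name == cl, ]
      match_detections(d, g, iou_thresh)$matches
    })
    n_gt <- sum(gt_all$class_name == cl)
    ap <- if (n_gt == 0) NA_real_ else {
      if (nrow(sweep) == 0) 0 else
        average_precision(sweep$score, sweep$tp, n_gt, interpolation)
    }
    tp <- sum(sweep$tp)
    tibble(class_name = cl, ap = ap, tp = tp, fp = nrow(sweep) - tp,
           fn = n_gt - tp, n_gt = n_gt)
  })
  structure(
    list(per_class = per_class,
         map = mean_ap(setNames(per_class$ap, per_class$class_name)),
         iou_thresh = iou_thresh,
         counts = tibble(tp = sum(per_class$tp), fp = sum(per_class$fp),
                         fn = sum(per_class$fn), tn = 0L)),
    class = "pv_eval"
  )
}

#' @export
print.pv_eval <- function(x, ...) {
  cat("<pv_eval> mAP@", x$iou_thresh, " = ", round(x$map, 4), "\n", sep = "")
  print(x$per_class)
  invisible(x)
}

#' @export
tidy.pv_eval <- function(x, ...) x$per_class

#' @export
glance.pv_eval <- function(x, ...) {
  tibble(map = x$map, precision = as.numeric(precision(x$counts)),
         recall = as.numeric(recall(x$counts)),
         n_classes = sum(!is.na(x$per_class$ap)), iou_thresh = x$iou_thresh)
}

#' Species-by-life-stage AP report
#'
#' Spreads per-class APs over a species x life-stage taxonomy (the pest
#' inventory labels each species/stage pair as its own detection class) and
#' flags the weakest and strongest cells. Cells absent from the taxonomy stay
#' `NA`, mirroring the sparsity of real inventories where not every stage of
#' every species is collected.
#'
#' @param eval_result a `pv_eval` object.
#' @param taxonomy tibble with `class_name`, `species`, `stage`.
#' @return A list with `table` (species x stage tibble of APs), `lowest` and
#'   `highest` (class names).
#' @export
subclass_report <- function(eval_result, taxonomy) {
  pc <- dplyr::inner_join(eval_result$per_class, taxonomy, by = "class_name")
  wide <- pc |>
    dplyr::select("species", "stage", "ap") |>
    tidyr::pivot_wider(names_from = "stage", values_from = "ap")
  defined <- pc[!is.na(pc$ap), ]
  list(
    table = wide,
    lowest = defined$class_name[which.min(defined$ap)],
    highest = defined$class_name[which.max(defined$ap)]
  )
}

#' PR curve for one class
#'
#' @param detections,gt_manifest,iou_thresh as in [evaluate_detections()].
#' @param class_name class to sweep.
#' @return A tibble of `threshold`, `recall`, `precision` points ordered by
#'   descending threshold (recall is non-decreasing along the sweep).
#' @export
pr_curve <- function(detections, gt_manifest, class_name, iou_thresh = 0.5) {
  gt_all <- purrr::map2_dfr(gt_manifest$image_id, gt_manifest$boxes,
                            ~ dplyr::mutate(.y, image_id = .x))
  sweep <- purrr::map_dfr(gt_manifest$image_id, function(id) {
    d <- detections[detections$image_id == id & detections$class_name == class_name, ]
    g <- gt_all[gt_all$image_id == id & gt_all$class_name == class_name, ]
    match_detections(d, g, iou_thresh)$matches
  })
  n_gt <- sum(gt_all$class_name == class_name)
  ord <- order(-sweep$score)
  tp_c <- cumsum(sweep$tp[ord])
  fp_c <- cumsum(!sweep$tp[ord])
  tibble(threshold = sweep$score[ord],
         recall = tp_c / max(n_gt, 1),
         precision = tp_c / (tp_c + fp_c))
}

#' Plot per-class AP of an evaluation
#'
#' @param object a `pv_eval` object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pv_eval <- function(object, ...) {
  d <- object$per_class[!is.na(object$per_class$ap), ]
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$class_name, .data$ap),
                                  y = .data$ap)) +
    ggplot2::geom_col(fill = "#2a9d8f") +
    ggplot2::geom_hline(yintercept = object$map, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste0("AP@", object$iou_thresh),
                  title = sprintf("mAP = %.3f", object$map)) +
    ggplot2::theme_minimal()
}
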