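#' Region-proposal network configuration
#'
#' The RPN slides a 3x3 window over the backbone feature map and, at every
#' position, scores and adjusts the anchor set (by default the K-means
#' clustered anchors, so all `K` anchors sit at each position). Proposals
#' are ranked by objectness, NMS-filtered and capped at `post_nms_top_n`
#' (about 2000 in the full-scale configuration).
#'
#' @param anchor_set an `anchor_set` (clustered centroids or preset grid).
#' @param feature_stride backbone stride in pixels (default 8 for the
#'   desk-scale profiles, 16 for full-scale backbones).
#' @param pre_nms_top_n,post_nms_top_n proposal budgets (defaults 6000/2000).
#' @param nms_thresh RPN NMS threshold (default 0.7).
#' @param pos_iou,neg_iou anchor labelling thresholds (defaults 0.7/0.3,
#'   `pos_iou > neg_iou`).
#' @return An `rpn_config` list.
#' @export
rpn_config <- function(anchor_set, feature_stride = 8L, pre_nms_top_n = 6000L,
                       post_nms_top_n = 2000L, nms_thresh = 0.7,
                       pos_iou = 0.7, neg_iou = 0.3) {
  if (pos_iou <= neg_iou) abort("pos_iou must exceed neg_iou")
  if (post_nms_top_n > pre_nms_top_n) abort("post_nms_top_n must be <= pre_nms_top_n")
  structure(list(anchor_set = anchor_set, feature_stride = as.integer(feature_stride),
                 pre_nms_top_n = as.integer(pre_nms_top_n),
                 post_nms_top_n = as.integer(post_nms_top_n),
                 nms_thresh = nms_thresh, pos_iou = pos_iou, neg_iou = neg_iou),
            class = "rpn_config")
}

#' Lay the anchor set over a feature map
#'
#' Places every anchor of the set at the image-coordinate center of each
#' feature cell, `(i + 0.5) * stride`, giving `feature_h * feature_w * K`
#' anchors on a regular stride-spaced lattice. Anchors may overhang the
#' image; clipping happens at proposal time.
#'
#' @param feature_h,feature_w feature map size in cells.
#' @param config an [rpn_config()].
#' @return A tibble of anchors `x1, y1, x2, y2` with `cell_x`, `cell_y`,
#'   `anchor_id`; ordered anchor-major within each cell, cells row-major.
#' @export
generate_anchors <- function(feature_h, feature_w, config) {
  stopifnot(feature_h > 0, feature_w > 0)
  K <- nrow(config$anchor_set)
  stride <- config$feature_stride
  grid <- expand.grid(anchor_id = seq_len(K), cell_x = 0:(feature_w - 1),
                      cell_y = 0:(feature_h - 1))
  cx <- (grid$cell_x + 0.5) * stride
  cy <- (grid$cell_y + 0.5) * stride
  w <- config$anchor_set$w[grid$anchor_id]
  h <- config$anchor_set$h[grid$anchor_id]
  tibble(x1 = cx - w / 2, y1 = cy - h / 2, x2 = cx + w / 2, y2 = cy + h / 2,
         cell_x = grid$cell_x, cell_y = grid$cell_y, anchor_id = grid$anchor_id)
}

#' Label anchors against ground truth and build regression targets
#'
#' An anchor is positive when its IoU with some ground-truth box reaches
#' `pos_iou`, or when it is the highest-IoU anchor for a ground truth (so
#' every ground truth owns at least one positive); negative when its best
#' IoU stays below `neg_iou`; ignored otherwise. Targets use the standard
#' parameterization relative to the anchor:
#' `tx = (gx - ax) / aw`, `ty = (gy - ay) / ah`, `tw = log(gw / aw)`,
#' `th = log(gh / ah)`.
#'
#' @param anchors anchor tibble from [generate_anchors()] (boxes may
#'   overhang the image).
#' @param gt_boxes ground-truth box tibble (may be empty: all negatives).
#' @param config an [rpn_config()].
#' @return A list: `labels` (`"pos"`, `"neg"`, `"ignore"`), `targets`
#'   (n x 4 matrix, rows meaningful for positives), `matched_gt` indices.
#' @export
label_anchors <- function(anchors, gt_boxes, config) {
  n <- nrow(anchors)
  labels <- rep("neg", n)
  targets <- matrix(0, n, 4, dimnames = list(NULL, c("tx", "ty", "tw", "th")))
  matched <- rep(NA_integer_, n)
  if (nrow(gt_boxes)) {
    m <- iou_matrix_cpp(as.matrix(anchors[, c("x1", "y1", "x2", "y2")]),
                        as.matrix(gt_boxes[, c("x1", "y1", "x2", "y2")]))
    best_iou <- apply(m, 1, max)
    best_gt <- max.col(m, ties.method = "first")
    labels[best_iou >= config$pos_iou] <- "pos"
    labels[best_iou < config$neg_iou] <- "neg"
    labels[best_iou >= config$neg_iou & best_iou < config$pos_iou] <- "ignore"
    labels[best_iou >= config$pos_iou] <- "pos"
    # argmax rule: every gt owns its best not-yet-claimed anchor, so two
    # ground truths sharing one argmax anchor still both get an owner
    claimed <- integer(0)
    for (j in order(-apply(m, 2, max))) {
      cand <- order(-m[, j])
      i <- cand[!(cand %in% claimed)][1]
      labels[i] <- "pos"
      best_gt[i] <- j
      claimed <- c(claimed, i)
    }
    pos <- labels == "pos"
    matched[pos] <- best_gt[pos]
    aw <- anchors$x2 - anchors$x1; ah <- anchors$y2 - anchors$y1
    ax <- (anchors$x1 + anchors$x2) / 2; ay <- (anchors$y1 + anchors$y2) / 2
    g <- gt_boxes[best_gt, ]
    gw <- g$x2 - g$x1; gh <- g$y2 - g$y1
    gx <- (g$x1 + g$x2) / 2; gy <- (g$y1 + g$y2) / 2
    targets[, 1] <- (gx - ax) / aw
    targets[, 2] <- (gy - ay) / ah
    targets[, 3] <- log(gw / aw)
    targets[, 4] <- log(gh / ah)
  }
  list(labels = labels, targets = targets, matched_gt = matched)
}

# Apply (tx, ty, tw, th) deltas to anchor/proposal boxes.
apply_deltas <- function(boxes, deltas) {
  w <- boxes$x2 - boxes$x1; h <- boxes$y2 - boxes$y1
  cx <- (boxes$x1 + boxes$x2) / 2 + deltas[, 1] * w
  cy <- (boxes$y1 + boxes$y2) / 2 + deltas[, 2] * h
  nw <- w * exp(pmin(deltas[, 3], 6))
  nh <- h * exp(pmin(deltas[, 4], 6))
  tibble(x1 = cx - nw / 2, y1 = cy - nh / 2, x2 = cx + nw / 2, y2 = cy + nh / 2)
}

#' Turn RPN outputs into ranked proposals
#'
#' Applies the predicted deltas to the laid-out anchors, clips to the image,
#' drops degenerate boxes, keeps the `pre_nms_top_n` highest-objectness
#' candidates, NMS-filters at `nms_thresh` (ties broken by anchor index) and
#' returns at most `post_nms_top_n` proposals sorted by descending
#' objectness.
#'
#' @param objectness numeric vector of anchor objectness logits or
#'   probabilities, aligned with `anchors` rows.
#' @param deltas n x 4 matrix of predicted adjustments.
#' @param anchors from [generate_anchors()].
#' @param config an [rpn_config()].
#' @param image_size square image side for clipping.
#' @return A proposal tibble `x1, y1, x2, y2, objectness`.
#' @export
propose <- function(objectness, deltas, anchors, config, image_size) {
  boxes <- apply_deltas(anchors, deltas)
  boxes$x1 <- pmin(pmax(boxes$x1, 0), image_size)
  boxes$x2 <- pmin(pmax(boxes$x2, 0), image_size)
  boxes$y1 <- pmin(pmax(boxes$y1, 0), image_size)
  boxes$y2 <- pmin(pmax(boxes$y2, 0), image_size)
  score <- as.numeric(objectness)
  ok <- boxes$x2 - boxes$x1 >= 1e-3 & boxes$y2 - boxes$y1 >= 1e-3
  boxes <- boxes[ok, ]; score <- score[ok]
  if (!nrow(boxes)) return(tibble(x1 = double(), y1 = double(), x2 = double(),
                                  y2 = double(), objectness = double()))
  ord <- order(-score, seq_along(score))[seq_len(min(config$pre_nms_top_n, length(score)))]
  boxes <- boxes[ord, ]; score <- score[ord]
  d <- dplyr::mutate(boxes, score = score, class_id = 0L)
  kept <- nms(d, config$nms_thresh, per_class = FALSE)
  kept <- head(kept, config$post_nms_top_n)
  tibble(x1 = kept$x1, y1 = kept$y1, x2 = kept$x2, y2 = kept$y2,
         objectness = kept$score)
}

#' ROI max pooling
#'
#' Maps each proposal to feature coordinates (division by the stride) and
#' max-pools it into an `output_size x output_size` grid per channel.
#' Proposals smaller than one feature cell pool from their containing cell.
#'
#' @param feature `Hf x Wf x C` feature array.
#' @param proposals proposal tibble in image coordinates.
#' @param output_size pooled grid side.
#' @param stride feature stride.
#' @return `output_size x output_size x C x n` array (attribute `idx` keeps
#'   argmax positions for the backward pass).
#' @export
roi_pool <- function(feature, proposals, output_size = 7L, stride = 8L) {
  rois <- as.matrix(proposals[, c("x1", "y1", "x2", "y2")]) / stride
  r <- roipool_cpp(feature, rois, as.integer(output_size))
  structure(r$out, idx = r$idx)
}

#' Specify and build the two-stage detector
#'
#' A compact Faster-RCNN-style pipeline with the clustered anchor set: a
#' residual backbone tapped at stride 8, a 3x3-window RPN scoring all `K`
#' anchors per position, ROI max pooling to a fixed grid, and a
#' fully-connected head with a `(num_classes + 1)`-way softmax (background
#' last) plus class-agnostic box refinement.
#'
#' @param num_classes foreground class count.
#' @param anchors an `anchor_set`; the RPN emits `K` boxes per position.
#' @param profile backbone profile (see [inc_yolo_spec()]).
#' @param input_size square input side.
#' @param roi_size pooled grid side (default 4 at desk scale).
#' @param head_dim hidden width of the box head.
#' @param rpn_channels 3x3 RPN tower width.
#' @param config an [rpn_config()]; defaults derive from `anchors`.
#' @return A `cluster_rcnn_spec`.
#' @export
cluster_rcnn_spec <- function(num_classes, anchors, profile = "tiny",
                              input_size = 64, roi_size = 4L, head_dim = 128L,
                              rpn_channels = NULL, config = NULL) {
  prof <- resolve_profile(profile)
  if (is.null(config)) config <- rpn_config(anchors, feature_stride = 8L)
  if (is.null(rpn_channels)) rpn_channels <- prof$widths[4]
  structure(list(num_classes = as.integer(num_classes), profile = prof,
                 anchors = anchors, config = config,
                 input_size = as.integer(input_size),
                 roi_size = as.integer(roi_size), head_dim = as.integer(head_dim),
                 rpn_channels = as.integer(rpn_channels)),
            class = "cluster_rcnn_spec")
}

#' @rdname cluster_rcnn_spec
#' @param spec a `cluster_rcnn_spec`.
#' @param seed initialization seed.
#' @export
build_cluster_rcnn <- function(spec, seed = 1L) {
  if (spec$input_size %% 8 != 0) abort("input smaller than one stride")
  prof <- spec$profile
  bb <- backbone_nodes(prof)
  # keep only nodes up to the stride-8 tap
  ids <- vapply(bb$nodes, `[[`, character(1), "id")
  keep <- seq_len(which(ids == bb$p3))
  K <- nrow(spec$anchors)
  feat_c <- prof$widths[4]
  nodes <- c(bb$nodes[keep], list(
    nn_node("rpn_tower", "conv", bb$p3, k = 3L, cin = feat_c,
            cout = spec$rpn_channels, act = "leaky"),
    nn_node("rpn_obj", "conv", "rpn_tower", k = 1L, cin = spec$rpn_channels,
            cout = K, act = "linear"),
    nn_node("rpn_delta", "conv", "rpn_tower", k = 1L, cin = spec$rpn_channels,
            cout = 4L * K, act = "linear")
  ))
  net <- nn_network(nodes, c(bb$p3, "rpn_obj", "rpn_delta"))
  params <- nn_init_params(net, seed)
  # box head parameters (outside the conv graph: per-ROI fully connected)
  din <- spec$roi_size^2 * feat_c
  head <- with_seed(derive_seed(seed, 17L), list(
    fc1 = list(W = matrix(rnorm(din * spec$head_dim, 0, sqrt(2 / din)),
                          din, spec$head_dim),
               b = numeric(spec$head_dim)),
    cls = list(W = matrix(rnorm(spec$head_dim * (spec$num_classes + 1), 0,
                                sqrt(2 / spec$head_dim)),
                          spec$head_dim, spec$num_classes + 1),
               b = numeric(spec$num_classes + 1)),
    bbox = list(W = matrix(rnorm(spec$head_dim * 4, 0, 0.001),
                           spec$head_dim, 4),
                b = numeric(4))
  ))
  structure(list(network = net, params = params, head = head, spec = spec,
                 feature_id = bb$p3),
            class = "pv_cluster_rcnn")
}

# Forward of the conv part; returns feature map, per-anchor objectness
# logits and deltas aligned with generate_anchors() row order.
rcnn_conv_forward <- function(model, image, keep_cache = FALSE) {
  fw <- nn_forward(model$network, model$params, image, keep_cache = keep_cache)
  feat <- fw$outs[[model$feature_id]]
  obj_map <- fw$outs[["rpn_obj"]]
  del_map <- fw$outs[["rpn_delta"]]
  S_h <- dim(obj_map)[1]; S_w <- dim(obj_map)[2]
  K <- nrow(model$spec$anchors)
  # anchor-major within cell, cells row-major (cell_y outer, cell_x inner)
  flat <- function(m, ch) as.numeric(aperm(m[, , ch, drop = FALSE], c(3, 2, 1)))
  obj <- as.numeric(aperm(obj_map, c(3, 2, 1)))          # k, x, y order
  deltas <- matrix(0, S_h * S_w * K, 4)
  for (d in 1:4) {
    deltas[, d] <- as.numeric(aperm(del_map[, , (seq_len(K) - 1) * 4 + d, drop = FALSE],
                                    c(3, 2, 1)))
  }
  list(fw = fw, feature = feat, objectness = obj, deltas = deltas,
       feature_h = S_h, feature_w = S_w)
}

# Box-head forward for pooled ROI features (rows = flattened ROIs).
rcnn_head_forward <- function(head, pooled_mat) {
  z1 <- sweep(pooled_mat %*% head$fc1$W, 2, head$fc1$b, `+`)
  a1 <- pmax(z1, 0)
  cls_logit <- sweep(a1 %*% head$cls$W, 2, head$cls$b, `+`)
  bbox <- sweep(a1 %*% head$bbox$W, 2, head$bbox$b, `+`)
  list(z1 = z1, a1 = a1, cls_logit = cls_logit, bbox = bbox)
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

#' Detect objects with the two-stage detector
#'
#' Runs backbone + RPN, ranks proposals ([propose()]), pools each proposal
#' ([roi_pool()]), classifies it over `num_classes + 1` (softmax scores sum
#' to 1, background last) and refines its box; background is suppressed and
#' per-class NMS applied.
#'
#' @param model a `pv_cluster_rcnn`.
#' @param image `H x W x 3` 8-bit array.
#' @param score_thresh confidence floor.
#' @param nms_iou final per-class NMS threshold.
#' @param class_names optional labels.
#' @param proposal_budget `c(pre, post)` NMS budgets at inference (defaults
#'   to the config's).
#' @return A detection tibble with `source = "cluster_rcnn"`.
#' @export
cluster_rcnn_detect <- function(model, image, score_thresh = 0.5, nms_iou = 0.45,
                                class_names = NULL, proposal_budget = NULL) {
  spec <- model$spec
  cfg <- spec$config
  if (!is.null(proposal_budget)) {
    cfg$pre_nms_top_n <- proposal_budget[1]
    cfg$post_nms_top_n <- proposal_budget[2]
  }
  cv <- rcnn_conv_forward(model, normalize_image(image))
  anchors <- generate_anchors(cv$feature_h, cv$feature_w, cfg)
  props <- propose(sigmoid(cv$objectness), cv$deltas, anchors, cfg, spec$input_size)
  if (!nrow(props)) return(empty_detections())
  pooled <- roi_pool(cv$feature, props, spec$roi_size, cfg$feature_stride)
  n <- nrow(props)
  pm <- matrix(as.numeric(pooled), n, spec$roi_size^2 * dim(cv$feature)[3], byrow = TRUE)
  hf <- rcnn_head_forward(model$head, pm)
  probs <- softmax_rows(hf$cls_logit)
  fg <- probs[, seq_len(spec$num_classes), drop = FALSE]
  refined <- apply_deltas(props, hf$bbox)
  refined$x1 <- pmin(pmax(refined$x1, 0), spec$input_size)
  refined$y1 <- pmin(pmax(refined$y1, 0), spec$input_size)
  refined$x2 <- pmin(pmax(refined$x2, 0), spec$input_size)
  refined$y2 <- pmin(pmax(refined$y2, 0), spec$input_size)
  cid <- max.col(fg, ties.method = "first")
  score <- fg[cbind(seq_len(n), cid)]
  dets <- tibble(
    x1 = refined$x1, y1 = refined$y1, x2 = refined$x2, y2 = refined$y2,
    class_id = as.integer(cid - 1L),
    class_name = if (!is.null(class_names)) class_names[cid] else as.character(cid - 1L),
    score = score, source = "cluster_rcnn"
  )
  dets <- dets[dets$score >= score_thresh & dets$x2 - dets$x1 > 1 &
                 dets$y2 - dets$y1 > 1, ]
  nms(dets, nms_iou)
}

# Matrix view of pooled ROI features: one row per ROI.
pooled_to_matrix <- function(pooled) {
  d <- dim(pooled)
  n <- if (length(d) == 4) d[4] else 1
  matrix(as.numeric(pooled), n, prod(d[1:3]), byrow = TRUE)
}
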