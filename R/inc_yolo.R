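#' Specify the Inception-augmented one-stage detector
#'
#' A YOLOv3-family detector: a residual backbone in the Darknet style with
#' three detection scales at strides 8, 16 and 32, top-down feature fusion by
#' 1x1 convolution + nearest upsampling + channel concatenation, and two
#' Inception blocks inserted immediately before the fusion concatenations —
#' variant B on the deepest (stride-32) map, where multi-layer convolution
#' has left limited detail, and variant A on the shallow (stride-8) map,
#' whose fine-grained features matter most for small objects. At every
#' fusion the lateral (low-level) path keeps twice the channels of the
#' upsampled high-level path (low:high = 2:1). Each scale's head emits
#' `anchors_per_scale * (5 + num_classes)` channels.
#'
#' Backbone profiles scale the same topology: `"darknet53"` is the full
#' 32-1024 channel network; `"small"` and `"tiny"` shrink widths and depth
#' so desk-scale training is a configuration choice, not a code change.
#'
#' @param num_classes number of object classes.
#' @param profile `"tiny"`, `"small"` or `"darknet53"`, or a list with
#'   `widths` (6 channel counts) and `blocks` (5 residual counts).
#' @param anchors an `anchor_set` (split across scales by area) or a list of
#'   3 anchor sets, shallow scale first.
#' @param input_size square input side; must be divisible by 32.
#' @param include_inception drop-in flag; `FALSE` builds the identical
#'   network with identity nodes in place of the Inception blocks.
#' @return An `inc_yolo_spec` list.
#' @export
inc_yolo_spec <- function(num_classes, profile = "tiny",
                          anchors = NULL, input_size = 64,
                          include_inception = TRUE) {
  if (input_size %% 32 != 0) abort("input_size must be divisible by 32")
  prof <- resolve_profile(profile)
  if (is.null(anchors)) {
    s <- input_size / 8
    anchors <- anchor_set(tibble(w = c(s * 0.8, s * 1.6, s * 3.2),
                                 h = c(s * 0.8, s * 1.6, s * 3.2)), "preset")
  }
  scales <- if (inherits(anchors, "anchor_set") || is.data.frame(anchors)) {
    split_anchors(anchor_set(anchors, origin = attr(anchors, "origin") %||% "preset"), 3)
  } else anchors
  a_per <- vapply(scales, nrow, integer(1))
  structure(list(num_classes = as.integer(num_classes), profile = prof,
                 anchors = scales, anchors_per_scale = a_per,
                 strides = c(8L, 16L, 32L), input_size = as.integer(input_size),
                 include_inception = include_inception),
            class = "inc_yolo_spec")
}

resolve_profile <- function(profile) {
  if (is.list(profile)) return(profile)
  switch(profile,
    tiny = list(name = "tiny", widths = c(8L, 16L, 32L, 32L, 48L, 64L),
                blocks = c(0L, 0L, 1L, 1L, 1L)),
    small = list(name = "small", widths = c(16L, 32L, 64L, 128L, 192L, 256L),
                 blocks = c(1L, 1L, 2L, 2L, 1L)),
    darknet53 = list(name = "darknet53",
                     widths = c(32L, 64L, 128L, 256L, 512L, 1024L),
                     blocks = c(1L, 2L, 8L, 8L, 4L)),
    abort(paste("unknown profile", profile))
  )
}

#' Split an anchor set across the three detection scales
#'
#' Anchors are sorted by area and dealt in thirds: the smallest to the
#' shallow high-resolution scale (stride 8), the largest to the deep scale
#' (stride 32). Uneven counts leave the extra anchors on the deeper scales.
#'
#' @param anchors an `anchor_set`.
#' @param n_scales number of detection scales (3).
#' @return A list of anchor sets, shallow first.
#' @export
split_anchors <- function(anchors, n_scales = 3) {
  ord <- order(anchors$w * anchors$h)
  sorted <- anchors[ord, ]
  n <- nrow(sorted)
  base <- n %/% n_scales
  extra <- n %% n_scales
  sizes <- rep(base, n_scales) + c(rep(0, n_scales - extra), rep(1, extra))
  out <- list()
  start <- 0
  for (i in seq_len(n_scales)) {
    out[[i]] <- anchor_set(sorted[(start + 1):(start + sizes[i]), ],
                           origin = attr(anchors, "origin") %||% "preset")
    start <- start + sizes[i]
  }
  out
}

# Residual backbone graph in the Darknet style. Returns nodes plus the ids
# of the stride-8/16/32 feature maps.
backbone_nodes <- function(prof) {
  w <- prof$widths
  nodes <- list(nn_node("in", "input"),
                nn_node("stem", "conv", "in", k = 3L, cin = 3L, cout = w[1], act = "leaky"))
  last <- "stem"
  taps <- character(3)
  for (s in 1:5) {
    did <- paste0("down", s)
    nodes <- c(nodes, list(nn_node(did, "conv", last, k = 3L, stride = 2L,
                                   cin = w[s], cout = w[s + 1], act = "leaky")))
    last <- did
    nb <- prof$blocks[s]
    for (b in seq_len(nb)) {
      r1 <- paste0("res", s, "_", b, "a")
      r2 <- paste0("res", s, "_", b, "b")
      ra <- paste0("res", s, "_", b)
      nodes <- c(nodes, list(
        nn_node(r1, "conv", last, k = 1L, cin = w[s + 1], cout = w[s + 1] %/% 2L, act = "leaky"),
        nn_node(r2, "conv", r1, k = 3L, cin = w[s + 1] %/% 2L, cout = w[s + 1], act = "leaky"),
        nn_node(ra, "add", c(r2, last))
      ))
      last <- ra
    }
    if (s >= 3) taps[s - 2] <- last
  }
  list(nodes = nodes, p3 = taps[1], p4 = taps[2], p5 = taps[3])
}

#' Build the one-stage detector
#'
#' Materializes an [inc_yolo_spec()] into a runnable network. The forward
#' contract on an `input_size` square image is three raw prediction maps of
#' spatial sizes `input_size / c(8, 16, 32)` and channel count
#' `anchors_per_scale * (5 + num_classes)` each.
#'
#' @param spec an `inc_yolo_spec`.
#' @param seed initialization seed.
#' @return A `pv_inc_yolo` with `$network`, `$params`, `$spec` and the head
#'   node ids `$heads` (shallow to deep).
#' @export
build_inc_yolo <- function(spec, seed = 1L) {
  w <- spec$profile$widths
  bb <- backbone_nodes(spec$profile)
  nodes <- bb$nodes
  nc <- spec$num_classes
  inc_ids <- character()

  add_inception <- function(nodes, prefix, input_id, variant, cin) {
    if (spec$include_inception) {
      isp <- inception_spec(variant, cin)
      frag <- inception_nodes(prefix, input_id, isp)
      inc_ids <<- c(inc_ids, vapply(frag$nodes, `[[`, character(1), "id"))
      list(nodes = c(nodes, frag$nodes), out = frag$out)
    } else {
      id <- paste0(prefix, "_skip")
      list(nodes = c(nodes, list(nn_node(id, "identity", input_id))), out = id)
    }
  }

  # deep scale: Inception B ahead of the fusion pathway
  incb <- add_inception(nodes, "incB", bb$p5, "B", w[6])
  nodes <- incb$nodes
  nodes <- c(nodes, list(
    nn_node("neck5", "conv", incb$out, k = 1L, cin = w[6], cout = w[6] %/% 2L, act = "leaky"),
    nn_node("head5_pre", "conv", "neck5", k = 3L, cin = w[6] %/% 2L, cout = w[6], act = "leaky"),
    nn_node("head_s32", "conv", "head5_pre", k = 1L, cin = w[6],
            cout = spec$anchors_per_scale[3] * (5L + nc), act = "linear"),
    # top-down route to stride 16; lateral keeps 2x the upsampled channels
    nn_node("route5", "conv", "neck5", k = 1L, cin = w[6] %/% 2L, cout = w[5] %/% 2L, act = "leaky"),
    nn_node("route5_up", "upsample", "route5", factor = 2L),
    nn_node("cat4", "concat", c(bb$p4, "route5_up")),
    nn_node("neck4", "conv", "cat4", k = 1L, cin = w[5] + w[5] %/% 2L,
            cout = w[5] %/% 2L, act = "leaky"),
    nn_node("head4_pre", "conv", "neck4", k = 3L, cin = w[5] %/% 2L, cout = w[5], act = "leaky"),
    nn_node("head_s16", "conv", "head4_pre", k = 1L, cin = w[5],
            cout = spec$anchors_per_scale[2] * (5L + nc), act = "linear")
  ))
  # shallow scale: Inception A on the lateral map ahead of the concatenation
  inca <- add_inception(nodes, "incA", bb$p3, "A", w[4])
  nodes <- inca$nodes
  nodes <- c(nodes, list(
    nn_node("route4", "conv", "neck4", k = 1L, cin = w[5] %/% 2L, cout = w[4] %/% 2L, act = "leaky"),
    nn_node("route4_up", "upsample", "route4", factor = 2L),
    nn_node("cat3", "concat", c(inca$out, "route4_up")),
    nn_node("neck3", "conv", "cat3", k = 1L, cin = w[4] + w[4] %/% 2L,
            cout = w[4] %/% 2L, act = "leaky"),
    nn_node("head3_pre", "conv", "neck3", k = 3L, cin = w[4] %/% 2L, cout = w[4], act = "leaky"),
    nn_node("head_s8", "conv", "head3_pre", k = 1L, cin = w[4],
            cout = spec$anchors_per_scale[1] * (5L + nc), act = "linear")
  ))
  net <- nn_network(nodes, c("head_s8", "head_s16", "head_s32"))
  structure(list(network = net, params = nn_init_params(net, seed), spec = spec,
                 heads = c("head_s8", "head_s16", "head_s32"),
                 inception_node_ids = inc_ids),
            class = "pv_inc_yolo")
}

#' Run the detector forward
#'
#' @param model a `pv_inc_yolo`.
#' @param image normalized `H x W x 3` array in `[-1, 1]`.
#' @param keep_cache keep layer caches for a backward pass.
#' @return List of the three raw head maps (named `head_s8`, `head_s16`,
#'   `head_s32`); with `keep_cache = TRUE`, the full forward state under
#'   `$fw`.
#' @export
inc_yolo_forward <- function(model, image, keep_cache = FALSE) {
  fw <- nn_forward(model$network, model$params, image, keep_cache = keep_cache)
  maps <- fw$outs[model$heads]
  if (keep_cache) list(maps = maps, fw = fw) else maps
}

#' Decode raw one-stage prediction maps into detections
#'
#' The YOLOv3 decode: at grid cell `(i, j)` with anchor `(aw, ah)`, the box
#' center is `((i + sigmoid(tx)) * stride, (j + sigmoid(ty)) * stride)`, the
#' size is `(aw * exp(tw), ah * exp(th))`, and the confidence is
#' `sigmoid(objectness) * sigmoid(class score)`. Detections above
#' `conf_thresh` go through per-class NMS at `nms_iou`.
#'
#' @param maps named list of raw head maps (from [inc_yolo_forward()]).
#' @param spec the detector's `inc_yolo_spec`.
#' @param conf_thresh confidence floor.
#' @param nms_iou NMS threshold.
#' @param class_names optional class labels.
#' @return A detection tibble with `source = "inc_yolo"`.
#' @export
decode_predictions <- function(maps, spec, conf_thresh = 0.25, nms_iou = 0.45,
                               class_names = NULL) {
  nc <- spec$num_classes
  img <- spec$input_size
  dets <- purrr::map_dfr(seq_along(maps), function(si) {
    m <- maps[[si]]
    anchors <- spec$anchors[[si]]
    stride <- spec$strides[si]
    S <- dim(m)[1]
    if (dim(m)[3] != nrow(anchors) * (5 + nc)) {
      abort("head channel count does not match anchors x (5 + classes)")
    }
    purrr::map_dfr(seq_len(nrow(anchors)), function(a) {
      off <- (a - 1) * (5 + nc)
      tx <- m[, , off + 1]; ty <- m[, , off + 2]
      tw <- m[, , off + 3]; th <- m[, , off + 4]
      obj <- sigmoid(m[, , off + 5])
      cls <- array(m[, , off + 5 + seq_len(nc)], dim = c(S, S, nc))
      # rows index y (j), cols index x (i)
      gx <- matrix(rep(0:(S - 1), each = S), S, S)
      gy <- matrix(rep(0:(S - 1), times = S), S, S)
      cx <- (gx + sigmoid(tx)) * stride
      cy <- (gy + sigmoid(ty)) * stride
      bw <- anchors$w[a] * exp(pmin(tw, 10))
      bh <- anchors$h[a] * exp(pmin(th, 10))
      cls_sig <- sigmoid(cls)
      best_c <- apply(cls_sig, c(1, 2), which.max)
      best_p <- apply(cls_sig, c(1, 2), max)
      score <- obj * best_p
      keep <- which(score >= conf_thresh)
      if (!length(keep)) return(empty_detections())
      tibble(
        x1 = pmax(0, cx[keep] - bw[keep] / 2), y1 = pmax(0, cy[keep] - bh[keep] / 2),
        x2 = pmin(img, cx[keep] + bw[keep] / 2), y2 = pmin(img, cy[keep] + bh[keep] / 2),
        class_id = as.integer(best_c[keep] - 1L),
        class_name = if (!is.null(class_names)) class_names[best_c[keep]]
                     else as.character(best_c[keep] - 1L),
        score = score[keep], source = "inc_yolo"
      )
    })
  })
  dets <- dets[dets$x2 > dets$x1 & dets$y2 > dets$y1, ]
  nms(dets, nms_iou)
}

#' @rdname decode_predictions
#' @export
empty_detections <- function() {
  tibble(x1 = double(), y1 = double(), x2 = double(), y2 = double(),
         class_id = integer(), class_name = character(),
         score = double(), source = character())
}

#' Encode ground-truth boxes onto the detection grids
#'
#' Each box is assigned to its best-IoU anchor (over all scales, sizes
#' compared co-centered) and to the grid cell containing its center at that
#' scale's stride; the regression targets invert the decode exactly, so
#' decode(encode(boxes)) reproduces the boxes. Anchor slots whose prior has
#' IoU above `ignore_iou` with any ground truth are masked out of the
#' no-object loss.
#'
#' @param boxes ground-truth box tibble.
#' @param spec an `inc_yolo_spec`.
#' @param ignore_iou no-object ignore threshold (default 0.5).
#' @return Per-scale list: `target` array shaped like the head map,
#'   `obj_mask`, `ignore_mask` (`S x S x A`), `box_scale` weights.
#' @export
encode_targets <- function(boxes, spec, ignore_iou = 0.5) {
  nc <- spec$num_classes
  img <- spec$input_size
  all_anchors <- dplyr::bind_rows(lapply(spec$anchors, as_tibble))
  scale_of <- rep(seq_along(spec$anchors), times = vapply(spec$anchors, nrow, integer(1)))
  index_in <- unlist(lapply(spec$anchors, function(a) seq_len(nrow(a))))
  out <- lapply(seq_along(spec$anchors), function(si) {
    S <- img %/% spec$strides[si]
    A <- nrow(spec$anchors[[si]])
    list(target = array(0, dim = c(S, S, A * (5 + nc))),
         obj_mask = array(FALSE, dim = c(S, S, A)),
         ignore_mask = array(FALSE, dim = c(S, S, A)),
         box_scale = array(1, dim = c(S, S, A)))
  })
  if (nrow(boxes)) {
    wh <- cbind(boxes$x2 - boxes$x1, boxes$y2 - boxes$y1)
    sim <- iou_wh(wh, as.matrix(all_anchors))
    best <- max.col(sim, ties.method = "first")
    for (bi in seq_len(nrow(boxes))) {
      si <- scale_of[best[bi]]
      a <- index_in[best[bi]]
      stride <- spec$strides[si]
      S <- img %/% stride
      cx <- (boxes$x1[bi] + boxes$x2[bi]) / 2
      cy <- (boxes$y1[bi] + boxes$y2[bi]) / 2
      ix <- min(max(floor(cx / stride), 0), S - 1)   # column (x)
      iy <- min(max(floor(cy / stride), 0), S - 1)   # row (y)
      off <- (a - 1) * (5 + nc)
      tx <- cx / stride - ix
      ty <- cy / stride - iy
      tw <- log(wh[bi, 1] / spec$anchors[[si]]$w[a])
      th <- log(wh[bi, 2] / spec$anchors[[si]]$h[a])
      out[[si]]$target[iy + 1, ix + 1, off + 1:4] <- c(tx, ty, tw, th)
      out[[si]]$target[iy + 1, ix + 1, off + 5] <- 1
      out[[si]]$target[iy + 1, ix + 1, off + 5 + boxes$class_id[bi] + 1] <- 1
      out[[si]]$obj_mask[iy + 1, ix + 1, a] <- TRUE
      out[[si]]$box_scale[iy + 1, ix + 1, a] <-
        2 - (wh[bi, 1] * wh[bi, 2]) / (img * img)
      # ignore other well-matching anchor slots at the box's cell
      for (sj in seq_along(spec$anchors)) {
        Sj <- img %/% spec$strides[sj]
        jx <- min(max(floor(cx / spec$strides[sj]), 0), Sj - 1)
        jy <- min(max(floor(cy / spec$strides[sj]), 0), Sj - 1)
        sims <- iou_wh(wh[bi, , drop = FALSE], as.matrix(spec$anchors[[sj]]))
        for (aj in which(sims[1, ] > ignore_iou)) {
          out[[sj]]$ignore_mask[jy + 1, jx + 1, aj] <- TRUE
        }
      }
    }
  }
  out
}

# Sigmoid cross-entropy with the target's own entropy subtracted (i.e. the
# binary KL divergence): non-negative, zero exactly at p = target, and with
# the usual gradient p - target wrt the logit. For hard 0/1 targets this is
# plain binary cross-entropy.
bce_sig <- function(logit, target) {
  p <- sigmoid(logit)
  eps <- 1e-9
  ent <- -(ifelse(target > 0, target * log(target + eps), 0) +
             ifelse(target < 1, (1 - target) * log(1 - target + eps), 0))
  list(loss = -(target * log(p + eps) + (1 - target) * log(1 - p + eps)) - ent,
       grad = p - target)
}

#' Multi-part one-stage detection loss
#'
#' The standard YOLOv3 composite: sigmoid cross-entropy on the in-cell
#' center offsets, squared error on the log width/height, sigmoid
#' cross-entropy objectness over every anchor slot (no-object slots
#' down-weighted by `noobj_weight`, well-matching non-assigned slots
#' ignored), and per-class sigmoid cross-entropy at assigned slots. Box
#' terms are weighted by `2 - area/img^2` so small objects are not drowned
#' out. Returns the analytic gradient with respect to each raw head map
#' alongside the scalar components.
#'
#' @param maps raw head maps.
#' @param targets from [encode_targets()].
#' @param spec the `inc_yolo_spec`.
#' @param coord_weight,noobj_weight loss weights.
#' @return List with `total`, `components` (box/obj/cls) and `grads` (named
#'   per-head gradient arrays).
#' @export
yolo_loss <- function(maps, targets, spec, coord_weight = 2, noobj_weight = 0.5) {
  nc <- spec$num_classes
  comp <- c(box = 0, obj = 0, cls = 0)
  grads <- list()
  for (si in seq_along(maps)) {
    m <- maps[[si]]
    if (any(!is.finite(m))) abort("NaN/Inf in prediction maps")
    tg <- targets[[si]]
    S <- dim(m)[1]
    A <- dim(m)[3] %/% (5 + nc)
    g <- array(0, dim = dim(m))
    for (a in seq_len(A)) {
      off <- (a - 1) * (5 + nc)
      pos <- tg$obj_mask[, , a]
      w <- tg$box_scale[, , a]
      # objectness: positives target 1; negatives target 0 unless ignored
      ob <- bce_sig(m[, , off + 5], as.numeric(pos))
      ow <- ifelse(pos, 1, ifelse(tg$ignore_mask[, , a], 0, noobj_weight))
      comp["obj"] <- comp["obj"] + sum(ob$loss * ow)
      g[, , off + 5] <- ob$grad * ow
      if (any(pos)) {
        for (d in 1:2) {
          xy <- bce_sig(m[, , off + d], tg$target[, , off + d])
          comp["box"] <- comp["box"] + coord_weight * sum(xy$loss[pos] * w[pos])
          gg <- array(0, dim = c(S, S))
          gg[pos] <- coord_weight * xy$grad[pos] * w[pos]
          g[, , off + d] <- gg
        }
        for (d in 3:4) {
          diff <- m[, , off + d] - tg$target[, , off + d]
          comp["box"] <- comp["box"] + coord_weight * 0.5 * sum(diff[pos]^2 * w[pos])
          gg <- array(0, dim = c(S, S))
          gg[pos] <- coord_weight * diff[pos] * w[pos]
          g[, , off + d] <- gg
        }
        for (ci in seq_len(nc)) {
          cl <- bce_sig(m[, , off + 5 + ci], tg$target[, , off + 5 + ci])
          comp["cls"] <- comp["cls"] + sum(cl$loss[pos])
          gg <- array(0, dim = c(S, S))
          gg[pos] <- cl$grad[pos]
          g[, , off + 5 + ci] <- gg
        }
      }
    }
    grads[[names(maps)[si]]] <- g
  }
  list(total = sum(comp), components = comp, grads = grads)
}

#' Detect objects in an image with the one-stage detector
#'
#' Normalizes the 8-bit image, runs the network and decodes detections.
#'
#' @param model a `pv_inc_yolo`.
#' @param image `H x W x 3` array with 0-255 values.
#' @inheritParams decode_predictions
#' @return A detection tibble.
#' @export
inc_yolo_detect <- function(model, image, conf_thresh = 0.25, nms_iou = 0.45,
                            class_names = NULL) {
  maps <- inc_yolo_forward(model, normalize_image(image))
  decode_predictions(maps, model$spec, conf_thresh, nms_iou, class_names)
}
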