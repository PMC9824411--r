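tiny_yolo <- function(num_classes = 3, input_size = 64, seed = 1,
                      include_inception = TRUE) {
  build_inc_yolo(inc_yolo_spec(num_classes, profile = "tiny",
                               input_size = input_size,
                               include_inception = include_inception),
                 seed = seed)
}

test_that("the three heads obey the anchors x (5 + classes) channel law", {
  m <- tiny_yolo(num_classes = 3, input_size = 64)
  maps <- inc_yolo_forward(m, array(rnorm(64 * 64 * 3, 0, 0.3), c(64, 64, 3)))
  expect_equal(dim(maps$head_s8), c(8, 8, 1 * (5 + 3)))
  expect_equal(dim(maps$head_s16), c(4, 4, 1 * (5 + 3)))
  expect_equal(dim(maps$head_s32), c(2, 2, 1 * (5 + 3)))
  # a 9-anchor set splits 3 per scale
  anch <- preset_anchor_set(c(8, 16, 32), c(0.5, 1, 2))
  spec <- inc_yolo_spec(37, profile = "tiny", anchors = anch, input_size = 96)
  m2 <- build_inc_yolo(spec, seed = 2)
  maps2 <- inc_yolo_forward(m2, array(rnorm(96 * 96 * 3, 0, 0.3), c(96, 96, 3)))
  expect_equal(dim(maps2$head_s8), c(12, 12, 3 * (5 + 37)))
  expect_equal(dim(maps2$head_s16), c(6, 6, 126))
  expect_equal(dim(maps2$head_s32), c(3, 3, 126))
  expect_error(inc_yolo_spec(3, input_size = 60), "divisible")
})

test_that("inception insertion is a drop-in: shapes unchanged, params differ by the module inventory", {
  with_inc <- tiny_yolo(seed = 5, include_inception = TRUE)
  without <- tiny_yolo(seed = 5, include_inception = FALSE)
  x <- array(rnorm(64 * 64 * 3, 0, 0.3), c(64, 64, 3))
  mi <- inc_yolo_forward(with_inc, x)
  mo <- inc_yolo_forward(without, x)
  expect_equal(lapply(mi, dim), lapply(mo, dim))
  p_with <- pestvision:::nn_count_params(with_inc$network)
  p_without <- pestvision:::nn_count_params(without$network)
  p_inc <- pestvision:::nn_count_params(with_inc$network,
                                        ids = with_inc$inception_node_ids)
  expect_gt(p_with, p_without)
  expect_equal(p_with - p_without, p_inc)
})

test_that("decoding raw zeros yields anchor-sized boxes at cell centers with score 0.25", {
  m <- tiny_yolo(num_classes = 2)
  spec <- m$spec
  maps <- list(head_s8 = array(0, c(8, 8, 7)),
               head_s16 = array(0, c(4, 4, 7)),
               head_s32 = array(0, c(2, 2, 7)))
  dets <- decode_predictions(maps, spec, conf_thresh = 0.2, nms_iou = 1.01)
  expect_true(all(abs(dets$score - 0.25) < 1e-12))
  # every surviving stride-32 box is anchor-sized and centered on its cell
  a32 <- spec$anchors[[3]]
  d32 <- dets[abs((dets$x2 - dets$x1) - a32$w[1]) < 1e-9 &
                dets$x1 > 0 & dets$x2 < 64, ]
  if (nrow(d32)) {
    cx <- (d32$x1 + d32$x2) / 2
    expect_true(all(abs((cx / 32) %% 1 - 0.5) < 1e-9))
  }
  # an impossible confidence threshold yields nothing
  expect_equal(nrow(decode_predictions(maps, spec, conf_thresh = 1.0)), 0)
})

test_that("NMS at decode keeps the top duplicate only", {
  d <- make_dets(data.frame(x1 = c(10, 10), y1 = c(10, 10), x2 = c(30, 30),
                            y2 = c(30, 30), score = c(0.9, 0.8)))
  out <- nms(d, 0.5)
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 0.9)
})

test_that("decode inverts encode for boxes on their best anchors", {
  m <- tiny_yolo(num_classes = 3, input_size = 64)
  spec <- m$spec
  boxes <- make_boxes(c(8, 12, 22, 24, 0), c(30, 34, 58, 60, 2))
  tg <- encode_targets(boxes, spec)
  # build raw maps whose sigmoids/exps reproduce the targets exactly
  logit <- function(p) log(pmin(pmax(p, 1e-9), 1 - 1e-9) / (1 - pmin(pmax(p, 1e-9), 1 - 1e-9)))
  maps <- list()
  for (si in 1:3) {
    t <- tg[[si]]$target
    raw <- array(-20, dim = dim(t))  # sigmoid(-20) ~ 0 for obj/cls background
    A <- dim(t)[3] / (5 + 3)
    for (a in seq_len(A)) {
      off <- (a - 1) * (5 + 3)
      pos <- tg[[si]]$obj_mask[, , a]
      if (!any(pos)) next
      for (d in 1:2) {
        plane <- raw[, , off + d]
        plane[pos] <- logit(t[, , off + d][pos])
        raw[, , off + d] <- plane
      }
      for (d in 3:4) {
        plane <- raw[, , off + d]
        plane[pos] <- t[, , off + d][pos]
        raw[, , off + d] <- plane
      }
      plane <- raw[, , off + 5]; plane[pos] <- 20; raw[, , off + 5] <- plane
      for (ci in 1:3) {
        plane <- raw[, , off + 5 + ci]
        plane[pos] <- ifelse(t[, , off + 5 + ci][pos] > 0.5, 20, -20)
        raw[, , off + 5 + ci] <- plane
      }
    }
    maps[[c("head_s8", "head_s16", "head_s32")[si]]] <- raw
  }
  dets <- decode_predictions(maps, spec, conf_thresh = 0.5, nms_iou = 0.45)
  expect_equal(nrow(dets), 2)
  dets <- dets[order(dets$x1), ]
  expect_equal(as.matrix(dets[, 1:4]), as.matrix(boxes[, 1:4]), tolerance = 1e-5)
  expect_equal(dets$class_id, boxes$class_id)
})

test_that("the loss is ~zero at the encoded fixed point and grows with box error", {
  m <- tiny_yolo(num_classes = 2)
  spec <- m$spec
  boxes <- make_boxes(c(10, 10, 30, 30, 1))
  tg <- encode_targets(boxes, spec)
  logit <- function(p) log(pmin(pmax(p, 1e-7), 1 - 1e-7) / (1 - pmin(pmax(p, 1e-7), 1 - 1e-7)))
  maps <- list()
  for (si in 1:3) {
    t <- tg[[si]]$target
    raw <- array(-30, dim = dim(t))
    A <- dim(t)[3] / 7
    for (a in seq_len(A)) {
      off <- (a - 1) * 7
      pos <- tg[[si]]$obj_mask[, , a]
      if (!any(pos)) next
      for (d in 1:2) { p <- raw[, , off + d]; p[pos] <- logit(t[, , off + d][pos]); raw[, , off + d] <- p }
      for (d in 3:4) { p <- raw[, , off + d]; p[pos] <- t[, , off + d][pos]; raw[, , off + d] <- p }
      p <- raw[, , off + 5]; p[pos] <- 30; raw[, , off + 5] <- p
      for (ci in 1:2) {
        p <- raw[, , off + 5 + ci]
        p[pos] <- ifelse(t[, , off + 5 + ci][pos] > 0.5, 30, -30)
        raw[, , off + 5 + ci] <- p
      }
    }
    maps[[c("head_s8", "head_s16", "head_s32")[si]]] <- raw
  }
  l0 <- yolo_loss(maps, tg, spec)
  expect_lt(l0$total, 1e-4)
  # doubling a width error never decreases the box term
  which_scale <- which(vapply(tg, function(t) any(t$obj_mask), logical(1)))[1]
  hid <- c("head_s8", "head_s16", "head_s32")[which_scale]
  pos_idx <- which(tg[[which_scale]]$obj_mask[, , 1])[1]
  S <- dim(maps[[hid]])[1]
  m1 <- maps; m1[[hid]][, , 3][pos_idx] <- m1[[hid]][, , 3][pos_idx] + 0.3
  m2 <- maps; m2[[hid]][, , 3][pos_idx] <- m2[[hid]][, , 3][pos_idx] + 0.6
  l1 <- yolo_loss(m1, tg, spec)$components["box"]
  l2 <- yolo_loss(m2, tg, spec)$components["box"]
  expect_gte(l2, l1)
  expect_gt(l1, l0$components["box"])
  expect_error(yolo_loss(list(head_s8 = array(NaN, dim(maps$head_s8)),
                              head_s16 = maps$head_s16,
                              head_s32 = maps$head_s32), tg, spec), "NaN")
})

test_that("loss gradients match finite differences on a small map", {
  spec <- inc_yolo_spec(2, input_size = 32)
  # 32 is not divisible by 32... use 64 with tiny grids instead
  spec <- inc_yolo_spec(2, input_size = 64)
  boxes <- make_boxes(c(12, 12, 28, 36, 0))
  tg <- encode_targets(boxes, spec)
  maps <- list(head_s8 = array(rnorm(8 * 8 * 7, 0, 0.5), c(8, 8, 7)),
               head_s16 = array(rnorm(4 * 4 * 7, 0, 0.5), c(4, 4, 7)),
               head_s32 = array(rnorm(2 * 2 * 7, 0, 0.5), c(2, 2, 7)))
  res <- yolo_loss(maps, tg, spec)
  for (hid in names(maps)) {
    idxs <- sample(length(maps[[hid]]), 10)
    for (i in idxs) {
      eps <- 1e-5
      mp <- maps; mp[[hid]][i] <- mp[[hid]][i] + eps
      mm <- maps; mm[[hid]][i] <- mm[[hid]][i] - eps
      num <- (yolo_loss(mp, tg, spec)$total - yolo_loss(mm, tg, spec)$total) / (2 * eps)
      expect_equal(res$grads[[hid]][i], num, tolerance = 1e-4)
    }
  }
})
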