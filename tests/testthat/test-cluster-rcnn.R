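demo_anchors <- function(k = 18) {
  anchor_set(tibble::tibble(w = seq(8, 50, length.out = k),
                            h = rev(seq(8, 50, length.out = k))))
}

test_that("anchor grids obey the H x W x K law on a stride lattice", {
  cfg <- rpn_config(demo_anchors(18), feature_stride = 32L)
  g <- generate_anchors(13, 13, cfg)
  expect_equal(nrow(g), 13 * 13 * 18)
  expect_equal(max(table(paste(g$cell_x, g$cell_y))), 18)
  one <- generate_anchors(1, 1, cfg)
  expect_equal(nrow(one), 18)
  expect_equal(unique((one$x1 + one$x2) / 2), 16)
  # centers form a regular stride-spaced lattice
  centers <- unique((g$x1 + g$x2) / 2)
  expect_equal(sort(centers), (0:12 + 0.5) * 32)
  for (hw in list(c(2, 5), c(7, 3))) {
    expect_equal(nrow(generate_anchors(hw[1], hw[2], cfg)), hw[1] * hw[2] * 18)
  }
})

test_that("anchor labelling follows the IoU thresholds and the argmax rule", {
  cfg <- rpn_config(demo_anchors(4), feature_stride = 8L)
  anchors <- tibble::tibble(x1 = c(0, 50, 5), y1 = c(0, 50, 5),
                            x2 = c(10, 60, 15), y2 = c(10, 60, 15),
                            cell_x = 0, cell_y = 0, anchor_id = 1:3)
  gt <- make_boxes(c(0, 0, 10, 10, 0))
  lab <- label_anchors(anchors, gt, cfg)
  expect_equal(lab$labels[1], "pos")
  expect_equal(lab$targets[1, ], c(tx = 0, ty = 0, tw = 0, th = 0))
  expect_equal(lab$labels[2], "neg")
  # parameterization arithmetic: anchor (0,0,10,10) vs gt (5,5,15,15)
  a2 <- tibble::tibble(x1 = 0, y1 = 0, x2 = 10, y2 = 10, cell_x = 0, cell_y = 0,
                       anchor_id = 1)
  g2 <- make_boxes(c(5, 5, 15, 15, 0))
  lab2 <- label_anchors(a2, g2, cfg)
  expect_equal(lab2$labels, "pos")  # argmax rule even though IoU < 0.7
  expect_equal(lab2$targets[1, ], c(tx = 0.5, ty = 0.5, tw = 0, th = 0))
  # no ground truth: everything negative
  lab3 <- label_anchors(anchors, empty_boxes(), cfg)
  expect_true(all(lab3$labels == "neg"))
})

test_that("every ground truth owns at least one positive anchor on random instances", {
  cfg <- rpn_config(demo_anchors(6), feature_stride = 8L)
  anchors <- generate_anchors(8, 8, cfg)
  with_seed_local(17, {
    for (i in 1:100) {
      n <- sample(1:5, 1)
      gt <- purrr::map_dfr(seq_len(n), function(j) {
        x1 <- runif(1, 0, 50); y1 <- runif(1, 0, 50)
        bbox(x1, y1, x1 + runif(1, 4, 14), y1 + runif(1, 4, 14))
      })
      lab <- label_anchors(anchors, gt, cfg)
      owned <- unique(lab$matched_gt[lab$labels == "pos"])
      expect_setequal(owned[!is.na(owned)], seq_len(n))
    }
  })
})

test_that("propose caps, clips, sorts and resolves ties deterministically", {
  k <- 4
  cfg <- rpn_config(demo_anchors(k), feature_stride = 8L,
                    pre_nms_top_n = 500L, post_nms_top_n = 40L, nms_thresh = 0.7)
  anchors <- generate_anchors(8, 8, cfg)
  n <- nrow(anchors)
  with_seed_local(3, {
    obj <- runif(n)
    props <- propose(obj, matrix(0, n, 4), anchors, cfg, 64)
    expect_lte(nrow(props), 40)
    expect_true(all(props$x1 >= 0 & props$x2 <= 64 & props$y1 >= 0 & props$y2 <= 64))
    expect_true(all(diff(props$objectness) <= 0))
    # zero deltas: surviving proposals coincide with (clipped) anchors
    clipped <- anchors
    clipped$x1 <- pmax(0, clipped$x1); clipped$y1 <- pmax(0, clipped$y1)
    clipped$x2 <- pmin(64, clipped$x2); clipped$y2 <- pmin(64, clipped$y2)
    best <- which.max(obj)
    expect_equal(unlist(props[1, c("x1", "y1", "x2", "y2")]),
                 unlist(clipped[best, c("x1", "y1", "x2", "y2")]))
    # identical scores: the smaller index survives NMS
    obj2 <- rep(0.5, n)
    p2 <- propose(obj2, matrix(0, n, 4), anchors, cfg, 64)
    p2b <- propose(obj2, matrix(0, n, 4), anchors, cfg, 64)
    expect_identical(p2, p2b)
  })
})

test_that("a proposal overflow is cut to exactly post_nms_top_n", {
  k <- 6
  cfg <- rpn_config(demo_anchors(k), feature_stride = 8L,
                    pre_nms_top_n = 6000L, post_nms_top_n = 100L, nms_thresh = 0.99)
  anchors <- generate_anchors(8, 8, cfg)
  with_seed_local(5, {
    props <- propose(runif(nrow(anchors)), matrix(rnorm(nrow(anchors) * 4, 0, 0.1),
                                                  ncol = 4), anchors, cfg, 64)
    expect_equal(nrow(props), 100)
  })
})

test_that("the detection head emits normalized class scores and respects thresholds", {
  anch <- demo_anchors(6)
  model <- build_cluster_rcnn(cluster_rcnn_spec(3, anch, input_size = 64), seed = 4)
  img <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  cv <- pestvision:::rcnn_conv_forward(model, normalize_image(img))
  props <- tibble::tibble(x1 = c(4, 30), y1 = c(4, 20), x2 = c(28, 60), y2 = c(30, 56))
  pooled <- roi_pool(cv$feature, props, model$spec$roi_size, 8L)
  hf <- pestvision:::rcnn_head_forward(model$head, pestvision:::pooled_to_matrix(pooled))
  probs <- pestvision:::softmax_rows(hf$cls_logit)
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, 2), tolerance = 1e-12)
  expect_equal(nrow(cluster_rcnn_detect(model, img, score_thresh = 1.0)), 0)
  d <- cluster_rcnn_detect(model, img, score_thresh = 0, proposal_budget = c(50L, 10L))
  if (nrow(d)) {
    expect_true(all(d$x1 >= 0 & d$x2 <= 64))
    expect_true(all(d$source == "cluster_rcnn"))
  }
})

test_that("rpn config invariants are enforced", {
  expect_error(rpn_config(demo_anchors(2), pos_iou = 0.3, neg_iou = 0.5), "exceed")
  expect_error(rpn_config(demo_anchors(2), pre_nms_top_n = 10L, post_nms_top_n = 20L),
               "<=")
  expect_error(build_cluster_rcnn(cluster_rcnn_spec(2, demo_anchors(2),
                                                    input_size = 4)), "stride")
})
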