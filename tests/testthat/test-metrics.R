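# Independent AP oracle: explicit PR sweep accumulating area rank by rank.
ap_oracle <- function(scores, is_tp, n_gt) {
  ord <- order(-scores, seq_along(scores))
  tp <- 0; fp <- 0; prev_r <- 0; area <- 0
  for (i in ord) {
    if (is_tp[i]) tp <- tp + 1 else fp <- fp + 1
    r <- tp / n_gt; p <- tp / (tp + fp)
    area <- area + p * (r - prev_r)
    prev_r <- r
  }
  area
}

test_that("match_detections handles perfect, empty and partial cases", {
  gts <- make_boxes(c(0, 0, 10, 10), c(30, 30, 50, 50))
  perfect <- make_dets(cbind(gts[, 1:4], score = c(0.9, 0.8)))
  r <- match_detections(perfect, gts)
  expect_equal(unlist(r$counts), c(tp = 2, fp = 0, fn = 0, tn = 0))
  r0 <- match_detections(make_dets(perfect[0, ]), gts)
  expect_equal(unlist(r0$counts[c("tp", "fn")]), c(tp = 0, fn = 2))
  # one detection overlapping a gt at IoU 0.6: 1 TP, 1 FN, 0 FP
  d <- make_dets(data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 7.5, score = 0.9))
  expect_equal(iou(d[, 1:4] |> dplyr::mutate(class_id = 0L, class_name = "0"),
                   gts[1, ]), 0.75, tolerance = 1e-12)
  r1 <- match_detections(d, gts, iou_thresh = 0.5)
  expect_equal(unlist(r1$counts), c(tp = 1, fp = 0, fn = 1, tn = 0))
})

test_that("precision and recall follow their defining ratios", {
  expect_equal(as.numeric(precision(list(tp = 8, fp = 2, fn = 0))), 0.8)
  expect_equal(as.numeric(recall(list(tp = 3, fp = 0, fn = 1))), 0.75)
  p0 <- precision(list(tp = 0, fp = 0, fn = 3))
  expect_equal(as.numeric(p0), 1)
  expect_true(attr(p0, "degenerate"))
})

test_that("average precision reproduces the hand-swept ranked case", {
  # ranked outcomes TP, FP, TP over 2 gts:
  # recall steps 0.5 and 1.0 at precisions 1 and 2/3 -> AP = 0.8333
  ap <- average_precision(scores = c(0.9, 0.8, 0.7), is_tp = c(TRUE, FALSE, TRUE),
                          n_gt = 2)
  expect_equal(ap, 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  expect_equal(average_precision(c(0.9, 0.8), c(TRUE, TRUE), 2), 1.0)
  expect_equal(average_precision(c(0.9), c(FALSE), 2), 0)
  expect_warning(average_precision(c(0.9), c(TRUE), 0), "undefined")
})

test_that("AP agrees with the brute-force PR-sweep oracle on random instances", {
  with_seed_local(7, {
    for (i in 1:200) {
      n <- sample(1:20, 1)
      n_gt <- sample(1:10, 1)
      scores <- runif(n)
      is_tp <- runif(n) < 0.5
      if (sum(is_tp) > n_gt) is_tp[which(is_tp)[seq_len(sum(is_tp) - n_gt)]] <- FALSE
      expect_equal(average_precision(scores, is_tp, n_gt),
                   ap_oracle(scores, is_tp, n_gt), tolerance = 1e-12)
    }
  })
})

test_that("AP depends on ranks only, and responds monotonically to edits", {
  scores <- c(0.9, 0.7, 0.5, 0.3); is_tp <- c(TRUE, FALSE, TRUE, FALSE)
  base <- average_precision(scores, is_tp, 3)
  expect_equal(average_precision(scores^3, is_tp, 3), base)     # monotone transform
  expect_equal(average_precision(scores * 0.5, is_tp, 3), base)
  # a duplicate FP never increases AP
  worse <- average_precision(c(scores, 0.8), c(is_tp, FALSE), 3)
  expect_lte(worse, base)
  # a new top-ranked TP never decreases AP
  better <- average_precision(c(scores, 0.95), c(is_tp, TRUE), 3)
  expect_gte(better, base)
})

test_that("mean_ap averages defined classes", {
  expect_equal(mean_ap(c(a = 1.0, b = 0.5)), 0.75)
  expect_equal(mean_ap(c(a = 0.42)), 0.42)
  expect_equal(mean_ap(c(a = 0.5, b = NA)), 0.5)
  expect_error(mean_ap(c(a = NA_real_)), "no class")
})

test_that("evaluate_detections matches an independent per-class recomputation", {
  with_seed_local(21, {
    man <- tiny_manifest(12, classes = c("a", "b", "c"))
    dets <- purrr::map_dfr(seq_len(nrow(man)), function(i) {
      b <- man$boxes[[i]]
      jit <- b
      jit$x1 <- pmax(0, jit$x1 - runif(1, 0, 4)); jit$x2 <- pmin(100, jit$x2 + runif(1, 0, 4))
      good <- dplyr::mutate(jit, score = runif(nrow(jit), 0.6, 1),
                            source = "inc_yolo", image_id = man$image_id[i])
      extra <- dplyr::mutate(b[sample(nrow(b), 1), ],
                             x1 = pmin(90, x1 + 40), x2 = pmin(100, x2 + 40),
                             score = runif(1, 0, 0.5), source = "inc_yolo",
                             image_id = man$image_id[i])
      dplyr::bind_rows(good, extra)
    })
    ev <- evaluate_detections(dets, man)
    # oracle: per class, re-run matching and the explicit sweep
    aps <- vapply(sort(unique(unlist(purrr::map(man$boxes, "class_name")))), function(cl) {
      sw <- purrr::map_dfr(seq_len(nrow(man)), function(i) {
        match_detections(dets[dets$image_id == man$image_id[i] & dets$class_name == cl, ],
                         man$boxes[[i]][man$boxes[[i]]$class_name == cl, ])$matches
      })
      n_gt <- sum(purrr::map_int(man$boxes, ~ sum(.x$class_name == cl)))
      ap_oracle(sw$score, sw$tp, n_gt)
    }, numeric(1))
    expect_equal(ev$map, mean(aps), tolerance = 1e-12)
    expect_true(ev$map >= 0 && ev$map <= 1)
  })
})

test_that("subclass_report spreads APs over the taxonomy and flags extremes", {
  ev <- structure(list(per_class = tibble::tibble(
    class_name = c("X (egg)", "X (adult)", "Y (larva)"),
    ap = c(0.3, 0.9, 0.6), tp = 1, fp = 0, fn = 0, n_gt = 1
  ), map = 0.6, iou_thresh = 0.5), class = "pv_eval")
  tax <- tibble::tibble(class_name = c("X (egg)", "X (adult)", "Y (larva)"),
                        species = c("X", "X", "Y"),
                        stage = c("egg", "adult", "larva"))
  rep <- subclass_report(ev, tax)
  expect_equal(rep$lowest, "X (egg)")
  expect_equal(rep$highest, "X (adult)")
  expect_true(is.na(rep$table$egg[rep$table$species == "Y"]))
})
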