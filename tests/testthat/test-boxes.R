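test_that("iou matches hand geometry and is symmetric", {
  b <- bbox(3, 4, 13, 24)
  expect_equal(iou(b, b), 1.0)
  expect_equal(iou(bbox(0, 0, 10, 10), bbox(20, 20, 30, 30)), 0)
  expect_equal(iou(bbox(0, 0, 2, 2), bbox(1, 1, 3, 3)), 1 / 7)
  a <- bbox(2, 2, 9, 7); c <- bbox(5, 1, 12, 9)
  expect_equal(iou(a, c), iou(c, a))
})

test_that("iou agrees with a pixel-rasterization oracle on integer boxes", {
  with_seed_local(42, {
    for (i in 1:50) {
      a <- sort(sample(0:63, 2)); while (a[1] == a[2]) a <- sort(sample(0:63, 2))
      ay <- sort(sample(0:63, 2)); while (ay[1] == ay[2]) ay <- sort(sample(0:63, 2))
      b <- sort(sample(0:63, 2)); while (b[1] == b[2]) b <- sort(sample(0:63, 2))
      by <- sort(sample(0:63, 2)); while (by[1] == by[2]) by <- sort(sample(0:63, 2))
      boxa <- c(a[1], ay[1], a[2], ay[2]); boxb <- c(b[1], by[1], b[2], by[2])
      expect_equal(iou(bbox(boxa[1], boxa[2], boxa[3], boxa[4]),
                       bbox(boxb[1], boxb[2], boxb[3], boxb[4])),
                   raster_iou(boxa, boxb), tolerance = 1e-12)
    }
  })
})

test_that("degenerate boxes are rejected", {
  expect_error(bbox(5, 5, 5, 10), "degenerate")
  expect_error(validate_boxes(tibble::tibble(x1 = 0, y1 = 0, x2 = 10, y2 = 10),
                              width = 8), "width")
  expect_error(bbox(-1, 0, 5, 5), ">= 0")
})

test_that("nms keeps the top scorer per overlap cluster, deterministically", {
  d <- make_dets(data.frame(
    x1 = c(0, 1, 50), y1 = c(0, 1, 50), x2 = c(10, 11, 60), y2 = c(10, 11, 60),
    score = c(0.9, 0.8, 0.7)
  ))
  out <- nms(d, 0.5)
  expect_equal(nrow(out), 2)
  expect_equal(out$score, c(0.9, 0.7))
  # different classes are not suppressed against each other
  d2 <- d; d2$class_id <- c(0L, 1L, 0L); d2$class_name <- as.character(d2$class_id)
  expect_equal(nrow(nms(d2, 0.5)), 3)
})

test_that("class_table counts image/class incidences", {
  m <- manifest(
    annotated_image("i1", 100, 100, make_boxes(c(0, 0, 10, 10, 0), c(20, 20, 30, 30, 1))),
    annotated_image("i2", 100, 100, make_boxes(c(0, 0, 10, 10, 0))),
    annotated_image("i3", 100, 100)
  )
  ct <- class_table(m)
  expect_equal(ct$n_images[ct$class_name == "0"], 2)
  expect_equal(ct$n_images[ct$class_name == "1"], 1)
  expect_equal(sum(ct$n_images), 3)  # incidences, not images
})

test_that("split_dataset partitions exhaustively, stratified, reproducibly", {
  m <- tiny_manifest(10)
  sp <- split_dataset(m, 0.7, seed = 11)
  expect_equal(nrow(sp$train), 7)
  expect_equal(nrow(sp$test), 3)
  expect_length(intersect(sp$train$image_id, sp$test$image_id), 0)
  expect_setequal(c(sp$train$image_id, sp$test$image_id), m$image_id)
  sp2 <- split_dataset(m, 0.7, seed = 11)
  expect_identical(sp$train$image_id, sp2$train$image_id)
  sp3 <- split_dataset(m, 0.7, seed = 12)
  expect_equal(nrow(sp3$train), 7)
  expect_false(identical(sort(sp$train$image_id), sort(sp3$train$image_id)))
  # tiny edge case
  sp4 <- split_dataset(tiny_manifest(2, classes = "a"), 0.5, seed = 1)
  expect_equal(c(nrow(sp4$train), nrow(sp4$test)), c(1, 1))
})

test_that("stratified split keeps per-class proportions within one image", {
  m <- tiny_manifest(40, classes = c("a", "b", "c", "d"))
  sp <- split_dataset(m, 0.7, seed = 3)
  strata <- purrr::map_chr(m$boxes, ~ .x$class_name[[1]])
  for (cl in unique(strata)) {
    n_cl <- sum(strata == cl)
    n_tr <- sum(purrr::map_chr(sp$train$boxes, ~ .x$class_name[[1]]) == cl)
    expect_lte(abs(n_tr - 0.7 * n_cl), 1)
  }
})
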