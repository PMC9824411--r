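test_that("photometric adjustment is the clamped affine map", {
  img <- array(c(0, 100, 250, 128), dim = c(2, 2, 1))
  expect_equal(photometric_adjust(img, 1, 0), img)
  expect_equal(photometric_adjust(array(250, c(1, 1, 1)), 1, 10)[1], 255)
  expect_equal(photometric_adjust(array(100, c(1, 1, 1)), 2, -30)[1], 170)
  expect_error(photometric_adjust(img, -1, 0), "positive")
  # affine composition law on unclamped pixels
  a <- 1.2; b <- 15
  lhs <- photometric_adjust(photometric_adjust(img, 1, b), a, 0)
  rhs <- photometric_adjust(img, a, a * b)
  expect_equal(lhs, rhs)
})

test_that("normalization maps 0..255 onto [-1, 1] and inverts", {
  expect_equal(normalize_image(0), -1)
  expect_equal(normalize_image(255), 1)
  expect_lt(abs(normalize_image(127.5)), 1 / 255)
  x <- array(runif(27, -1, 1), c(3, 3, 3))
  expect_equal(normalize_image(denormalize_image(x)), x, tolerance = 1e-12)
})

test_that("rotation transforms boxes by the corner hull", {
  img <- array(runif(100 * 100 * 3, 0, 255), c(100, 100, 3))
  b <- make_boxes(c(10, 20, 30, 40))
  r0 <- random_rotate(img, b, 0)
  expect_equal(r0$boxes, b)
  expect_equal(r0$image, img)
  r90 <- random_rotate(img, b, 90)
  expect_equal(unlist(r90$boxes[1, 1:4]), c(x1 = 20, y1 = 70, x2 = 40, y2 = 90))
  # 180 twice is the identity on boxes (within a pixel)
  r180 <- random_rotate(img, b, 180)
  rback <- random_rotate(r180$image, r180$boxes, 180)
  expect_true(all(abs(as.matrix(rback$boxes[, 1:4]) - as.matrix(b[, 1:4])) < 1))
  # boxes rotated out of frame are dropped
  corner <- make_boxes(c(0, 0, 8, 8))
  rot <- random_rotate(img, corner, 45)
  expect_true(nrow(rot$boxes) <= 1)
  if (nrow(rot$boxes)) {
    validate_boxes(rot$boxes, width = 100, height = 100)
  }
})

test_that("mirror flips reflect coordinates and preserve areas", {
  img <- array(seq_len(100 * 100 * 3), c(100, 100, 3))
  b <- make_boxes(c(0, 0, 10, 10), c(30, 40, 50, 90))
  fh <- mirror_flip(img, b, "horizontal")
  expect_equal(unlist(fh$boxes[1, 1:4]), c(x1 = 90, y1 = 0, x2 = 100, y2 = 10))
  areas <- function(x) (x$x2 - x$x1) * (x$y2 - x$y1)
  expect_equal(areas(fh$boxes), areas(b))
  # double flip is the identity for image and boxes
  fh2 <- mirror_flip(fh$image, fh$boxes, "horizontal")
  expect_equal(fh2$image, img)
  expect_equal(fh2$boxes, b)
  fv2 <- mirror_flip(mirror_flip(img, b, "vertical")$image,
                     mirror_flip(img, b, "vertical")$boxes, "vertical")
  expect_equal(fv2$boxes, b)
})

test_that("density labels follow count and overlap rules", {
  expect_equal(density_label(empty_boxes()), "A")
  expect_equal(density_label(make_boxes(c(10, 10, 30, 30))), "A")
  expect_equal(density_label(make_boxes(c(0, 0, 10, 10), c(50, 50, 60, 60))), "A")
  dense <- dplyr::bind_rows(lapply(0:11, function(i) {
    bbox(5 * i, 5 * i, 5 * i + 20, 5 * i + 20)
  }))
  expect_equal(density_label(dense), "D")
  mid <- dplyr::bind_rows(lapply(0:3, function(i) bbox(25 * i, 0, 25 * i + 20, 20)))
  expect_equal(density_label(mid), "B")
})

test_that("a seeded augmentation chain is byte-reproducible", {
  img <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  b <- make_boxes(c(10, 10, 30, 30))
  p1 <- augment_params(seed = 77)
  p2 <- augment_params(seed = 77)
  expect_identical(p1, p2)
  a1 <- apply_augmentation(img, b, p1)
  a2 <- apply_augmentation(img, b, p2)
  expect_identical(a1, a2)
  # surviving boxes always stay inside the frame
  for (s in 1:10) {
    res <- apply_augmentation(img, b, augment_params(seed = s, rotate_prob = 1))
    if (nrow(res$boxes)) validate_boxes(res$boxes, width = 64, height = 64)
  }
})
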