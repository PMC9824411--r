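#' Photometric contrast/brightness adjustment
#'
#' Applies the affine photometric transform `output = alpha * input + beta`
#' pixelwise to an 8-bit image (values 0-255), clamping the result back into
#' `[0, 255]`. `alpha` is contrast (must be positive), `beta` is brightness
#' in 8-bit units. Before clamping the transform is affine, so
#' `adjust(alpha, 0)` after `adjust(1, beta)` equals `adjust(alpha,
#' alpha * beta)` on unclamped pixels.
#'
#' @param image numeric array (any shape) with 8-bit values in `[0, 255]`.
#' @param alpha positive contrast factor.
#' @param beta additive brightness shift.
#' @return The adjusted image, same shape, values in `[0, 255]`.
#' @export
photometric_adjust <- function(image, alpha = 1, beta = 0) {
  if (!is.numeric(alpha) || alpha <= 0) abort("alpha (contrast) must be positive")
  out <- alpha * image + beta
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

#' Normalize an 8-bit image to \[-1, 1\]
#'
#' `v -> v / 127.5 - 1`, the symmetric rescaling used before feeding images
#' to the networks; [denormalize_image()] is its inverse.
#'
#' @param image numeric array with values in `[0, 255]`.
#' @return Array of the same shape with values in `[-1, 1]`.
#' @export
normalize_image <- function(image) image / 127.5 - 1

#' @rdname normalize_image
#' @export
denormalize_image <- function(image) (image + 1) * 127.5

#' Rotate an image and its boxes about a center point
#'
#' The image is rotated by `angle` degrees about `center` (default: the image
#' center) with bilinear resampling into a canvas of the same size;
#' out-of-frame samples are filled with `fill`. Each box is replaced by the
#' axis-aligned hull of its four rotated corners, clipped to the image; boxes
#' whose clipped area falls below `min_visible` of the original area are
#' dropped (a rotated-out label is meaningless).
#'
#' @param image `H x W x C` numeric array (0-255).
#' @param boxes box tibble.
#' @param angle rotation in degrees (positive rotates image content
#'   counter-clockwise on screen).
#' @param center length-2 `(x, y)` rotation center in pixels.
#' @param fill fill value for samples from outside the frame.
#' @param min_visible minimum surviving area fraction for a box to be kept.
#' @return A list with `image` and `boxes`.
#' @export
random_rotate <- function(image, boxes = empty_boxes(), angle = 0,
                          center = NULL, fill = 0, min_visible = 0.2) {
  stopifnot(is.finite(angle))
  d <- dim(image)
  H <- d[1]; W <- d[2]; C <- if (length(d) >= 3) d[3] else 1
  if (is.null(center)) center <- c(W / 2, H / 2)
  cx <- center[1]; cy <- center[2]
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  # forward corner map: (x,y) -> (cx + ct*(x-cx) + st*(y-cy),
  #                               cy - st*(x-cx) + ct*(y-cy))
  rot_img <- image
  if (angle %% 360 != 0) {
    # inverse map for resampling: rotate output pixel centers by -angle
    xo <- rep(seq_len(W) - 0.5, each = H)
    yo <- rep(seq_len(H) - 0.5, times = W)
    xs <- cx + ct * (xo - cx) - st * (yo - cy)
    ys <- cy + st * (xo - cx) + ct * (yo - cy)
    x0 <- floor(xs - 0.5); y0 <- floor(ys - 0.5)
    fx <- xs - 0.5 - x0; fy <- ys - 0.5 - y0
    gather <- function(xi, yi, ch) {
      ok <- xi >= 0 & xi <= W - 1 & yi >= 0 & yi <= H - 1
      v <- rep(fill, length(xi))
      lin <- (yi + 1) + H * xi + H * W * (ch - 1)
      v[ok] <- image[lin[ok]]
      v
    }
    rot_img <- array(0, dim = c(H, W, C))
    for (ch in seq_len(C)) {
      v00 <- gather(x0, y0, ch); v10 <- gather(x0 + 1, y0, ch)
      v01 <- gather(x0, y0 + 1, ch); v11 <- gather(x0 + 1, y0 + 1, ch)
      v <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
        (1 - fx) * fy * v01 + fx * fy * v11
      rot_img[, , ch] <- matrix(v, H, W)
    }
    if (length(d) == 2) rot_img <- rot_img[, , 1]
  }
  new_boxes <- boxes[0, ]
  if (nrow(boxes)) {
    rows <- purrr::map_dfr(seq_len(nrow(boxes)), function(i) {
      b <- boxes[i, ]
      px <- c(b$x1, b$x2, b$x1, b$x2)
      py <- c(b$y1, b$y1, b$y2, b$y2)
      qx <- cx + ct * (px - cx) + st * (py - cy)
      qy <- cy - st * (px - cx) + ct * (py - cy)
      nb <- b
      nb$x1 <- max(0, min(qx)); nb$x2 <- min(W, max(qx))
      nb$y1 <- max(0, min(qy)); nb$y2 <- min(H, max(qy))
      area0 <- (b$x2 - b$x1) * (b$y2 - b$y1)
      area1 <- max(0, nb$x2 - nb$x1) * max(0, nb$y2 - nb$y1)
      if (area1 < min_visible * area0) nb[0, ] else nb
    })
    new_boxes <- rows
  }
  list(image = rot_img, boxes = new_boxes)
}

#' Mirror-flip an image and its boxes
#'
#' Horizontal flips reflect x coordinates (`x1' = W - x2`, `x2' = W - x1`),
#' vertical flips reflect y. Flipping twice along the same axis is the
#' identity, and box areas are preserved exactly.
#'
#' @param image `H x W x C` numeric array.
#' @param boxes box tibble.
#' @param axis `"horizontal"` (left-right) or `"vertical"` (up-down).
#' @return A list with `image` and `boxes`.
#' @export
mirror_flip <- function(image, boxes = empty_boxes(),
                        axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  img <- image
  if (axis == "horizontal") {
    idx <- rev(seq_len(W))
    img <- if (length(d) >= 3) image[, idx, , drop = FALSE] else image[, idx]
    if (nrow(boxes)) {
      new_x1 <- W - boxes$x2
      boxes$x2 <- W - boxes$x1
      boxes$x1 <- new_x1
    }
  } else {
    idx <- rev(seq_len(H))
    img <- if (length(d) >= 3) image[idx, , , drop = FALSE] else image[idx, ]
    if (nrow(boxes)) {
      new_y1 <- H - boxes$y2
      boxes$y2 <- H - boxes$y1
      boxes$y1 <- new_y1
    }
  }
  list(image = img, boxes = boxes)
}

#' Label scene crowding from sparse (A) to dense (D)
#'
#' Combines the object count (cut-points 1-2, 3-5, 6-9, 10+) with the
#' maximum pairwise box IoU: any strictly positive overlap lifts the label to
#' at least B, and overlap at or above `overlap_iou_thresh` lifts it to at
#' least C. Empty and single-object images are A. Deterministic.
#'
#' @param img a one-row manifest tibble or a box tibble.
#' @param overlap_iou_thresh IoU marking substantial overlap (default 0.2).
#' @return `"A"`, `"B"`, `"C"` or `"D"`.
#' @export
density_label <- function(img, overlap_iou_thresh = 0.2) {
  boxes <- if (is.data.frame(img) && "boxes" %in% names(img)) img$boxes[[1]] else img
  n <- nrow(boxes)
  if (n <= 1) return("A")
  m <- iou_matrix_cpp(as.matrix(boxes[, c("x1", "y1", "x2", "y2")]),
                      as.matrix(boxes[, c("x1", "y1", "x2", "y2")]))
  diag(m) <- 0
  max_iou <- max(m)
  count_level <- findInterval(n, c(3, 6, 10)) + 1L
  overlap_level <- if (max_iou <= 0) 1L else if (max_iou < overlap_iou_thresh) 2L else 3L
  c("A", "B", "C", "D")[max(count_level, overlap_level)]
}

#' Sample a random augmentation policy
#'
#' Draws the parameters of one augmentation application: contrast
#' `alpha ~ U(alpha_range)`, brightness `beta ~ U(beta_range)` (8-bit units),
#' a flip with probability `flip_prob` (axis chosen uniformly), and with
#' probability `rotate_prob` a rotation angle `~ U(-rotation_max_deg,
#' rotation_max_deg)` about the image center.
#'
#' @param seed integer seed; the full chain is reproducible from it.
#' @param alpha_range,beta_range photometric ranges.
#' @param rotation_max_deg maximal absolute rotation angle.
#' @param flip_prob,rotate_prob application probabilities.
#' @return A list of parameters consumable by [apply_augmentation()].
#' @export
augment_params <- function(seed = NULL, alpha_range = c(0.7, 1.3),
                           beta_range = c(-30, 30), rotation_max_deg = 15,
                           flip_prob = 0.5, rotate_prob = 0.3) {
  draw <- function() {
    list(
      alpha = runif(1, alpha_range[1], alpha_range[2]),
      beta = runif(1, beta_range[1], beta_range[2]),
      angle = if (runif(1) < rotate_prob) runif(1, -rotation_max_deg, rotation_max_deg) else 0,
      flip = if (runif(1) < flip_prob) sample(c("horizontal", "vertical"), 1) else "none"
    )
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Apply an augmentation chain to an image and its boxes
#'
#' Fixed order: photometric adjustment first (on 8-bit values), then the
#' geometric transforms (rotation, then flip); normalization to `[-1, 1]` is
#' applied afterwards by the training loop, so geometry operates on the
#' original value range. All surviving boxes stay inside the image.
#'
#' @param image `H x W x C` 8-bit array.
#' @param boxes box tibble.
#' @param params from [augment_params()].
#' @return A list with `image` and `boxes`.
#' @export
apply_augmentation <- function(image, boxes, params) {
  img <- photometric_adjust(image, params$alpha, params$beta)
  out <- list(image = img, boxes = boxes)
  if (!is.null(params$angle) && params$angle != 0) {
    out <- random_rotate(out$image, out$boxes, params$angle)
  }
  if (!is.null(params$flip) && params$flip != "none") {
    out <- mirror_flip(out$image, out$boxes, params$flip)
  }
  out
}
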