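#' Bounding-box tibbles
#'
#' Boxes are rows of a tibble with columns `x1`, `y1`, `x2`, `y2` (0-based,
#' half-open pixel corner coordinates, so a box covers `[x1, x2) x [y1, y2)`),
#' `class_id` (non-negative integer) and `class_name`. Detections add `score`
#' (confidence in `[0, 1]`) and `source` (`"inc_yolo"`, `"cluster_rcnn"` or
#' `"ensemble"`). All geometry in the package flows through this one
#' convention; format dialects are converted at the I/O boundary.
#'
#' @param x1,y1,x2,y2 numeric corner coordinates, `x2 > x1`, `y2 > y1`.
#' @param class_id non-negative integer class index (0-based).
#' @param class_name character class label; defaults to `class_id` as text.
#' @return A tibble with one row per box.
#' @examples
#' bbox(0, 0, 10, 10, class_id = 0, class_name = "aphid")
#' @export
bbox <- function(x1, y1, x2, y2, class_id = 0L, class_name = as.character(class_id)) {
  b <- tibble(
    x1 = as.double(x1), y1 = as.double(y1),
    x2 = as.double(x2), y2 = as.double(y2),
    class_id = as.integer(class_id), class_name = as.character(class_name)
  )
  validate_boxes(b)
  b
}

#' Validate a box tibble
#'
#' Checks the package's box invariants: finite, non-negative coordinates with
#' strictly positive width and height (degenerate zero-area boxes are
#' rejected, not dropped).
#'
#' @param boxes a box tibble (see [bbox()]).
#' @param width,height optional image bounds; when given, every box must lie
#'   inside `[0, width) x [0, height)` (i.e. `x2 <= width`, `y2 <= height`).
#' @param context character prefix for error messages (e.g. an image id).
#' @return `boxes`, invisibly.
#' @export
validate_boxes <- function(boxes, width = NULL, height = NULL, context = NULL) {
  ctx <- if (is.null(context)) "" else paste0("[", context, "] ")
  need <- c("x1", "y1", "x2", "y2")
  if (!all(need %in% names(boxes))) {
    abort(paste0(ctx, "box table must have columns x1, y1, x2, y2"))
  }
  m <- as.matrix(boxes[, need])
  if (nrow(m) == 0) return(invisible(boxes))
  if (any(!is.finite(m))) abort(paste0(ctx, "box coordinates must be finite"))
  if (any(m < 0)) abort(paste0(ctx, "box coordinates must be >= 0"))
  bad <- which(boxes$x2 <= boxes$x1 | boxes$y2 <= boxes$y1)
  if (length(bad)) {
    abort(paste0(ctx, "degenerate (zero-area) box at record ",
                 paste(bad, collapse = ", ")))
  }
  if (!is.null(width) && any(boxes$x2 > width + 1e-6)) {
    abort(paste0(ctx, "box exceeds image width ", width))
  }
  if (!is.null(height) && any(boxes$y2 > height + 1e-6)) {
    abort(paste0(ctx, "box exceeds image height ", height))
  }
  if ("class_id" %in% names(boxes) && any(boxes$class_id < 0)) {
    abort(paste0(ctx, "class_id must be non-negative"))
  }
  invisible(boxes)
}

#' Intersection over union of bounding boxes
#'
#' The similarity behind detection matching, non-maximum suppression, anchor
#' labelling and the anchor-clustering distance: the area of overlap divided
#' by the area of union. Symmetric, in `[0, 1]`, and 1 exactly when the two
#' boxes coincide.
#'
#' @param a,b box tibbles (or data frames with `x1, y1, x2, y2`). When both
#'   have a single row a scalar is returned, otherwise the
#'   `nrow(a) x nrow(b)` matrix of pairwise IoUs.
#' @return Scalar or matrix of IoU values in `[0, 1]`.
#' @examples
#' iou(bbox(0, 0, 2, 2), bbox(1, 1, 3, 3)) # 1/7
#' @export
iou <- function(a, b) {
  validate_boxes(a)
  validate_boxes(b)
  m <- iou_matrix_cpp(as.matrix(a[, c("x1", "y1", "x2", "y2")]),
                      as.matrix(b[, c("x1", "y1", "x2", "y2")]))
  if (nrow(a) == 1 && nrow(b) == 1) m[1, 1] else m
}

# IoU of width/height pairs treated as co-centered boxes; the distance
# 1 - iou_wh() is the anchor-clustering metric. a, b: matrices with cols w, h.
iou_wh <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  iw <- outer(a[, 1], b[, 1], pmin)
  ih <- outer(a[, 2], b[, 2], pmin)
  inter <- iw * ih
  inter / (outer(a[, 1] * a[, 2], b[, 1] * b[, 2], `+`) - inter)
}

#' Greedy non-maximum suppression
#'
#' Keeps the highest-scoring detection, removes any lower-scoring detection
#' of the same class overlapping it with IoU above `iou_thresh`, and repeats.
#' Ties in score are broken by input order, so the result is deterministic.
#'
#' @param detections a detection tibble with box columns and `score`.
#' @param iou_thresh IoU above which a lower-scoring overlap is suppressed.
#' @param per_class suppress within each `class_id` separately (default) or
#'   across classes.
#' @return The surviving detections, sorted by descending score.
#' @export
nms <- function(detections, iou_thresh = 0.45, per_class = TRUE) {
  if (nrow(detections) == 0) return(detections)
  groups <- if (per_class && "class_id" %in% names(detections)) {
    split(seq_len(nrow(detections)), detections$class_id)
  } else list(seq_len(nrow(detections)))
  keep <- integer(0)
  for (g in groups) {
    d <- detections[g, ]
    ord <- order(-d$score, seq_len(nrow(d)))
    m <- iou_matrix_cpp(as.matrix(d[, c("x1", "y1", "x2", "y2")]),
                        as.matrix(d[, c("x1", "y1", "x2", "y2")]))
    alive <- rep(TRUE, length(ord))
    for (i in seq_along(ord)) {
      if (!alive[i]) next
      later <- ord[seq_along(ord) > i]
      sup <- later[m[ord[i], later] > iou_thresh]
      alive[match(sup, ord)] <- FALSE
    }
    keep <- c(keep, g[ord[alive]])
  }
  out <- detections[keep, ]
  out[order(-out$score, seq_len(nrow(out))), ]
}

#' Annotated images and dataset manifests
#'
#' An annotated image couples an image id and pixel dimensions with its
#' ground-truth box table and an optional crowding label (`"A"` sparse to
#' `"D"` dense). A manifest is a tibble with one row per image and a `boxes`
#' list-column; rendered pixel data, when present, lives in an `image`
#' list-column and annotation files on disk are referenced by `path`.
#'
#' @param image_id character id.
#' @param width,height positive integer pixel dimensions.
#' @param boxes box tibble; every box must lie within the image.
#' @param density_class `"A"`, `"B"`, `"C"`, `"D"` or `NA`.
#' @param image optional `height x width x 3` numeric array (0-255).
#' @param path optional path to the image file.
#' @return `annotated_image()`: a one-row manifest tibble; `manifest()`: a
#'   manifest tibble binding its arguments.
#' @export
annotated_image <- function(image_id, width, height, boxes = empty_boxes(),
                            density_class = NA_character_, image = NULL,
                            path = NA_character_) {
  stopifnot(width > 0, height > 0)
  validate_boxes(boxes, width = width, height = height, context = image_id)
  tibble(
    image_id = as.character(image_id),
    width = as.integer(width), height = as.integer(height),
    density_class = density_class, path = path,
    boxes = list(boxes), image = list(image)
  )
}

#' @rdname annotated_image
#' @param ... one-row image tibbles or manifests to bind.
#' @export
manifest <- function(...) {
  dplyr::bind_rows(...)
}

#' @rdname annotated_image
#' @export
empty_boxes <- function() {
  tibble(x1 = double(), y1 = double(), x2 = double(), y2 = double(),
         class_id = integer(), class_name = character())
}

#' Per-class image counts of a manifest
#'
#' Counts, for each class, the number of images in which that class occurs at
#' least once (an image containing two classes is counted under both, so the
#' totals equal the number of image/class incidences).
#'
#' @param manifest a manifest tibble.
#' @return A tibble with `class_name` and `n_images`.
#' @export
class_table <- function(manifest) {
  incidences <- purrr::map2_dfr(manifest$image_id, manifest$boxes, function(id, b) {
    if (nrow(b) == 0) return(tibble(image_id = character(), class_name = character()))
    tibble(image_id = id, class_name = unique(b$class_name))
  })
  if (nrow(incidences) == 0) return(tibble(class_name = character(), n_images = integer()))
  incidences |>
    dplyr::count(.data$class_name, name = "n_images") |>
    dplyr::arrange(.data$class_name)
}

#' Stratified train/test split
#'
#' Splits a manifest into disjoint, exhaustive train and test parts,
#' stratified by each image's first (dominant) class so that per-class
#' proportions stay within one image of the target fraction. The train side
#' is rounded half-up per class and then reconciled to
#' `round(train_fraction * N)` overall. Deterministic for a given seed.
#'
#' @param manifest a manifest tibble.
#' @param train_fraction fraction of images for training, in (0, 1). The
#'   default 0.7 is the conventional 7:3 train/test split.
#' @param seed integer RNG seed.
#' @return A list with manifests `train` and `test`.
#' @export
split_dataset <- function(manifest, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- nrow(manifest)
  if (n < 2) abort("need at least 2 images to split")
  strata <- purrr::map_chr(manifest$boxes, function(b) {
    if (nrow(b) == 0) "" else b$class_name[[1]]
  })
  empties <- names(which(table(strata[strata != ""]) == 0))
  if (length(empties)) warn(paste("classes with 0 images:", paste(empties, collapse = ", ")))
  round_half_up <- function(x) floor(x + 0.5)
  target_total <- round_half_up(train_fraction * n)
  classes <- sort(unique(strata))
  sizes <- vapply(classes, function(s) sum(strata == s), integer(1))
  k <- round_half_up(train_fraction * sizes)
  # reconcile per-class rounding drift with the global target, adjusting the
  # classes whose rounded count sits farthest from the exact fraction so no
  # class moves more than one image off target
  drift <- sum(k) - target_total
  if (drift != 0) {
    excess <- k - train_fraction * sizes
    ord <- order(if (drift > 0) -excess else excess, classes)
    for (i in seq_len(abs(drift))) {
      j <- ord[(i - 1) %% length(ord) + 1]
      k[j] <- k[j] - sign(drift)
    }
  }
  with_seed(seed, {
    take <- logical(n)
    for (j in seq_along(classes)) {
      idx <- which(strata == classes[j])
      pick <- max(0L, min(length(idx), k[j]))
      take[idx[sample.int(length(idx), pick)]] <- TRUE
    }
  })
  list(train = manifest[take, ], test = manifest[!take, ])
}
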