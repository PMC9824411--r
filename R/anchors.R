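#' K-means clustering of box sizes under the IoU distance
#'
#' Clusters ground-truth box (width, height) pairs with Lloyd-style K-means
#' using `d(box, centroid) = 1 - IoU(box, centroid)` where the IoU is taken
#' with both boxes co-centered — the established metric for designing anchor
#' boxes, and scale-aware in a way Euclidean distance on (w, h) is not.
#' Initialization is farthest-point (K-means++ style under the IoU distance)
#' from a seeded RNG; the best of `restarts` runs is returned. Boxes are
#' canonically sorted before seeding so the result is invariant to input
#' order. Empty clusters are re-seeded from the box farthest from its
#' centroid. Because the median (or mean) update is not guaranteed to lower
#' the IoU objective monotonically, the best partition-induced iterate seen
#' is kept. For tiny instances (at most ~20,000 possible assignments) the
#' global optimum is found by exhaustive search instead of Lloyd iteration.
#'
#' @param boxes a two-column matrix/data frame of widths and heights, or a
#'   manifest tibble (box sizes are then extracted via [box_population()]).
#' @param k number of centroids, `2 <= k <= nrow(boxes)` (k = 1 allowed).
#' @param seed integer seed; restart `r` uses a seed derived from it.
#' @param restarts independent initializations (default 10).
#' @param max_iter Lloyd iteration cap.
#' @param tol stop when the mean IoU improves by less than this.
#' @param update `"median"` (robust, default) or `"mean"` centroid update.
#' @param warm_start optional centroid matrix included as an extra
#'   initialization (used by [sweep_k()] to make the mIoU-vs-K curve
#'   non-decreasing).
#' @return An object of class `pv_cluster`: list with `k`, `centroids`
#'   (tibble `w`, `h`, sorted by area), `mean_iou`, `assignments`,
#'   `iterations`, `origin = "clustered"`.
#' @export
kmeans_iou <- function(boxes, k, seed = 1L, restarts = 10L, max_iter = 100L,
                       tol = 1e-6, update = c("median", "mean"),
                       warm_start = NULL) {
  update <- match.arg(update)
  wh <- as_wh_matrix(boxes)
  if (any(wh <= 0)) abort("box dimensions must be positive")
  if (k < 1) abort("k must be >= 1")
  if (k > nrow(wh)) abort(paste0("k (", k, ") exceeds number of boxes (", nrow(wh), ")"))
  # canonical sort: permutation invariance given the seed strategy
  ord <- order(wh[, 1], wh[, 2])
  wh <- wh[ord, , drop = FALSE]

  f <- if (update == "median") median else mean
  # Centroids induced by an assignment, and the re-assignment objective of
  # those centroids. Only such partition-induced states are reported, so the
  # converged objective is comparable with an exhaustive search over
  # assignments.
  induced <- function(assign, sim) {
    cen <- matrix(0, k, 2)
    for (j in seq_len(k)) {
      members <- wh[assign == j, , drop = FALSE]
      if (nrow(members) == 0) {
        # re-seed an empty cluster from the worst-covered box
        cen[j, ] <- wh[which.min(apply(sim, 1, max)), ]
      } else {
        cen[j, ] <- c(f(members[, 1]), f(members[, 2]))
      }
    }
    cen
  }

  run_once <- function(init) {
    cen <- init
    best <- NULL
    prev_obj <- -Inf
    for (it in seq_len(max_iter)) {
      sim <- iou_wh(wh, cen)
      assign <- max.col(sim, ties.method = "first")
      cen <- induced(assign, sim)
      sim2 <- iou_wh(wh, cen)
      assign2 <- max.col(sim2, ties.method = "first")
      obj <- mean(sim2[cbind(seq_len(nrow(wh)), assign2)])
      if (is.null(best) || obj > best$mean_iou) {
        best <- list(centroids = cen, mean_iou = obj, assignments = assign2,
                     iterations = it)
      }
      if (obj - prev_obj < tol && it > 1) break
      prev_obj <- obj
    }
    best
  }

  farthest_point_init <- function(rseed) {
    with_seed(rseed, {
      cen <- matrix(0, k, 2)
      cen[1, ] <- wh[sample.int(nrow(wh), 1), ]
      if (k > 1) for (j in 2:k) {
        d <- 1 - apply(iou_wh(wh, cen[seq_len(j - 1), , drop = FALSE]), 1, max)
        p <- d^2
        cen[j, ] <- if (sum(p) <= 0) wh[sample.int(nrow(wh), 1), ] else
          wh[sample.int(nrow(wh), 1, prob = p), ]
      }
      cen
    })
  }

  n <- nrow(wh)
  if (k^n <= 20000 && is.null(warm_start)) {
    # tiny instance: global optimum by exhaustive search over assignments
    best <- NULL
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
    for (r in seq_len(nrow(grid))) {
      assign <- grid[r, ]
      if (length(unique(assign)) < k) next
      cen <- t(vapply(seq_len(k), function(j) {
        c(f(wh[assign == j, 1]), f(wh[assign == j, 2]))
      }, numeric(2)))
      sim <- iou_wh(wh, cen)
      a2 <- max.col(sim, ties.method = "first")
      obj <- mean(sim[cbind(seq_len(n), a2)])
      if (is.null(best) || obj > best$mean_iou) {
        best <- list(centroids = cen, mean_iou = obj, assignments = a2,
                     iterations = 1L)
      }
    }
  } else {
    inits <- lapply(seq_len(restarts), function(r) farthest_point_init(derive_seed(seed, r)))
    if (!is.null(warm_start)) inits <- c(inits, list(as_wh_matrix(warm_start)))
    results <- lapply(inits, run_once)
    best <- results[[which.max(vapply(results, `[[`, numeric(1), "mean_iou"))]]
  }
  area_ord <- order(best$centroids[, 1] * best$centroids[, 2], best$centroids[, 1])
  assignments <- integer(nrow(wh))
  assignments[ord] <- match(best$assignments, area_ord)
  structure(
    list(k = k,
         centroids = tibble(w = best$centroids[area_ord, 1],
                            h = best$centroids[area_ord, 2]),
         mean_iou = best$mean_iou,
         assignments = assignments,
         iterations = best$iterations,
         origin = "clustered"),
    class = "pv_cluster"
  )
}

as_wh_matrix <- function(boxes) {
  if (is.data.frame(boxes) && all(c("boxes", "image_id") %in% names(boxes))) {
    boxes <- box_population(boxes)
  }
  if (is.data.frame(boxes)) {
    if (all(c("w", "h") %in% names(boxes))) {
      boxes <- cbind(boxes$w, boxes$h)
    } else if (all(c("x1", "x2") %in% names(boxes))) {
      boxes <- cbind(boxes$x2 - boxes$x1, boxes$y2 - boxes$y1)
    } else boxes <- as.matrix(boxes)
  }
  m <- matrix(as.numeric(boxes), ncol = 2)
  colnames(m) <- c("w", "h")
  m
}

#' @export
print.pv_cluster <- function(x, ...) {
  cat("<pv_cluster> k =", x$k, " mean IoU =", round(x$mean_iou, 4), "\n")
  print(x$centroids)
  invisible(x)
}

#' @export
tidy.pv_cluster <- function(x, ...) {
  dplyr::mutate(x$centroids, cluster = dplyr::row_number(), .before = 1)
}

#' @export
glance.pv_cluster <- function(x, ...) {
  tibble(k = x$k, mean_iou = x$mean_iou, iterations = x$iterations)
}

#' Sweep the number of anchor clusters
#'
#' Runs [kmeans_iou()] for every K in `[k_min, k_max]`, warm-starting each K
#' with the previous solution plus a farthest point (so the best-of-restarts
#' mean IoU is non-decreasing in K), and reports the marginal mIoU gain per
#' step to support reading the elbow of the curve. On pest-style box
#' populations the curve levels off at the K matching the number of distinct
#' size modes.
#'
#' @inheritParams kmeans_iou
#' @param k_min,k_max sweep range (defaults 2 and 20).
#' @return An object of class `pv_sweep`: list of `pv_cluster` results plus a
#'   `summary` tibble with `k`, `mean_iou`, `gain`.
#' @export
sweep_k <- function(boxes, k_min = 2L, k_max = 20L, seed = 1L, restarts = 10L,
                    max_iter = 100L, update = "median") {
  wh <- as_wh_matrix(boxes)
  if (k_max > nrow(wh)) abort("k_max exceeds the number of boxes")
  results <- list()
  prev <- NULL
  for (k in k_min:k_max) {
    warm <- if (!is.null(prev)) {
      cen <- as.matrix(prev$centroids)
      d <- 1 - apply(iou_wh(wh, cen), 1, max)
      rbind(cen, wh[which.max(d), ])
    } else NULL
    res <- kmeans_iou(wh, k, seed = derive_seed(seed, k), restarts = restarts,
                      max_iter = max_iter, update = update, warm_start = warm)
    # keep the curve monotone: the (K-1) centroids plus one extra centroid on
    # the worst-covered box can never score worse than the (K-1) solution
    if (!is.null(prev) && res$mean_iou < prev$mean_iou) {
      res <- eval_centroid_set(wh, warm)
    }
    results[[as.character(k)]] <- res
    prev <- res
  }
  miou <- vapply(results, `[[`, numeric(1), "mean_iou")
  structure(
    list(results = results,
         summary = tibble(k = k_min:k_max, mean_iou = unname(miou),
                          gain = c(NA, diff(unname(miou))))),
    class = "pv_sweep"
  )
}

# Score a fixed centroid set against the box population (no refitting).
eval_centroid_set <- function(wh, cen) {
  sim <- iou_wh(wh, cen)
  assign <- max.col(sim, ties.method = "first")
  area_ord <- order(cen[, 1] * cen[, 2], cen[, 1])
  structure(
    list(k = nrow(cen),
         centroids = tibble(w = cen[area_ord, 1], h = cen[area_ord, 2]),
         mean_iou = mean(sim[cbind(seq_len(nrow(wh)), assign)]),
         assignments = match(assign, area_ord), iterations = 0L,
         origin = "clustered"),
    class = "pv_cluster"
  )
}

#' @export
print.pv_sweep <- function(x, ...) {
  cat("<pv_sweep> K in [", min(x$summary$k), ",", max(x$summary$k), "]\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.pv_sweep <- function(x, ...) x$summary

#' Plot the mIoU-vs-K curve of a cluster sweep
#'
#' @param object a `pv_sweep` object.
#' @param ... unused.
#' @return A ggplot of mean IoU against K (the elbow plot).
#' @export
autoplot.pv_sweep <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$k, y = .data$mean_iou)) +
    ggplot2::geom_line(color = "#264653") +
    ggplot2::geom_point(color = "#e76f51") +
    ggplot2::labs(x = "number of anchor clusters K", y = "mean IoU") +
    ggplot2::theme_minimal()
}

#' Preset anchor grid from scales and aspect ratios
#'
#' The classical region-proposal anchor design: the cross product of scales
#' `s` (anchor area `s^2`) and aspect ratios `r = w/h`, with `w = s * sqrt(r)`
#' and `h = s / sqrt(r)` so each anchor's area is exactly `s^2`. The default
#' grid is the four scales 64/128/256/512 crossed with ratios 1/2, 1, 2
#' (12 anchors); the clustered alternative (e.g. K = 18 centroids) comes from
#' [kmeans_iou()].
#'
#' @param sizes positive anchor scales in pixels.
#' @param ratios positive aspect ratios (w/h).
#' @return An `anchor_set`: tibble with `w`, `h` and attribute
#'   `origin = "preset"`.
#' @export
preset_anchor_set <- function(sizes = c(64, 128, 256, 512), ratios = c(1 / 2, 1, 2)) {
  if (!length(sizes) || !length(ratios) || any(sizes <= 0) || any(ratios <= 0)) {
    abort("sizes and ratios must be non-empty and positive")
  }
  grid <- expand.grid(s = sizes, r = ratios)
  anchor_set(tibble(w = grid$s * sqrt(grid$r), h = grid$s / sqrt(grid$r)),
             origin = "preset")
}

#' @rdname preset_anchor_set
#' @param anchors a tibble/matrix of `w`, `h` pairs (e.g. cluster centroids).
#' @param origin `"preset"` or `"clustered"`.
#' @export
anchor_set <- function(anchors, origin = "clustered") {
  m <- as_wh_matrix(anchors)
  if (nrow(m) == 0 || any(m <= 0)) abort("anchors must be non-empty with positive dims")
  structure(tibble(w = m[, 1], h = m[, 2]), origin = origin,
            class = c("anchor_set", class(tibble())))
}

#' @rdname preset_anchor_set
#' @param x a `pv_cluster` result.
#' @export
as_anchor_set <- function(x) {
  if (inherits(x, "pv_cluster")) return(anchor_set(x$centroids, origin = "clustered"))
  anchor_set(x)
}
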