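# Brute-force K-means-IoU oracle: enumerate every assignment of boxes to k
# clusters, update centroids per the same rule, and keep the best objective.
brute_force_kmeans <- function(wh, k, update = "median") {
  n <- nrow(wh)
  best <- -Inf
  grid <- expand.grid(rep(list(seq_len(k)), n))
  f <- if (update == "median") stats::median else mean
  for (r in seq_len(nrow(grid))) {
    assign <- as.integer(grid[r, ])
    if (length(unique(assign)) < k) next
    cen <- t(vapply(seq_len(k), function(j) {
      c(f(wh[assign == j, 1]), f(wh[assign == j, 2]))
    }, numeric(2)))
    sim <- pestvision:::iou_wh(wh, cen)
    obj <- mean(apply(sim, 1, max))
    if (obj > best) best <- obj
  }
  best
}

test_that("kmeans_iou solves trivial and separable instances", {
  same <- matrix(rep(c(10, 20), each = 6), ncol = 2)
  r <- kmeans_iou(same, 1, seed = 1)
  expect_equal(unlist(r$centroids), c(w = 10, h = 20))
  expect_equal(r$mean_iou, 1.0)
  distinct <- rbind(c(10, 10), c(40, 20), c(100, 100))
  r3 <- kmeans_iou(distinct, 3, seed = 1)
  expect_equal(r3$mean_iou, 1.0)
  expect_error(kmeans_iou(distinct, 5), "exceeds")
  expect_error(kmeans_iou(rbind(c(-2, 5)), 1), "positive")
})

test_that("three well-separated size modes are recovered within 10%", {
  with_seed_local(5, {
    modes <- rbind(c(12, 12), c(60, 40), c(200, 220))
    wh <- do.call(rbind, lapply(1:3, function(m) {
      sweep(matrix(runif(200, 0.95, 1.05), 100, 2), 2, modes[m, ], `*`)
    }))
    r3 <- kmeans_iou(wh, 3, seed = 2)
    got <- as.matrix(r3$centroids)[order(r3$centroids$w), ]
    expect_true(all(abs(got - modes) / modes < 0.10))
    r2 <- kmeans_iou(wh, 2, seed = 2)
    expect_gt(r3$mean_iou, r2$mean_iou)
  })
})

test_that("converged objective equals the brute-force optimum on tiny instances", {
  with_seed_local(99, {
    for (trial in 1:12) {
      n <- sample(4:7, 1)
      k <- sample(2:3, 1)
      wh <- matrix(runif(2 * n, 5, 120), n, 2)
      ours <- kmeans_iou(wh, k, seed = trial, restarts = 40)$mean_iou
      oracle <- brute_force_kmeans(wh, k)
      expect_gte(ours + 1e-9, oracle - 1e-9)
      expect_equal(ours, oracle, tolerance = 1e-6)
    }
  })
})

test_that("mean IoU is invariant to uniform rescaling and box order", {
  with_seed_local(31, {
    wh <- matrix(runif(40, 8, 300), 20, 2)
    a <- kmeans_iou(wh, 4, seed = 9)
    b <- kmeans_iou(wh * 3.7, 4, seed = 9)
    expect_equal(a$mean_iou, b$mean_iou, tolerance = 1e-9)
    p <- kmeans_iou(wh[sample(20), ], 4, seed = 9)
    expect_equal(a$mean_iou, p$mean_iou, tolerance = 1e-12)
    expect_equal(as.matrix(a$centroids), as.matrix(p$centroids), tolerance = 1e-12)
  })
})

test_that("sweep is non-decreasing and exact at k = number of distinct sizes", {
  with_seed_local(13, {
    wh <- matrix(runif(24, 10, 200), 12, 2)
    sw <- sweep_k(wh, k_min = 2, k_max = 12, seed = 4, restarts = 4)
    expect_true(all(diff(sw$summary$mean_iou) >= -1e-9))
    expect_equal(sw$summary$mean_iou[sw$summary$k == 12], 1.0, tolerance = 1e-9)
    expect_equal(sw$summary$gain[-1], diff(sw$summary$mean_iou), tolerance = 1e-12)
  })
})

test_that("preset anchor grid is the size x ratio cross product with exact areas", {
  a <- preset_anchor_set()
  expect_equal(nrow(a), 12)
  expect_equal(attr(a, "origin"), "preset")
  grid <- expand.grid(s = c(64, 128, 256, 512), r = c(1 / 2, 1, 2))
  expect_true(all(abs(a$w * a$h - grid$s^2) < 1e-6))
  expect_equal(a$w / a$h, grid$r, tolerance = 1e-12)
  one <- preset_anchor_set(64, 1)
  expect_equal(unname(c(one$w, one$h)), c(64, 64))
  expect_error(preset_anchor_set(c(-64), 1), "positive")
})
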