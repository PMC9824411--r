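# Gradient correctness of the hand-written layers, checked against central
# finite differences on tiny tensors.

numeric_grad <- function(fn, x, eps = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

simple_net <- function() {
  pestvision:::nn_network(list(
    pestvision:::nn_node("in", "input"),
    pestvision:::nn_node("c1", "conv", "in", k = 3L, cin = 2L, cout = 3L, act = "leaky"),
    pestvision:::nn_node("p1", "maxpool", "c1", k = 2L, stride = 2L, pad = 0L),
    pestvision:::nn_node("c2", "conv", "p1", k = 1L, cin = 3L, cout = 2L, act = "linear")
  ), "c2")
}

test_that("conv graph gradients match finite differences", {
  net <- simple_net()
  params <- pestvision:::nn_init_params(net, seed = 3)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  loss_of <- function(p, xx) {
    out <- pestvision:::nn_forward(net, p, xx, keep_cache = FALSE)$outs[["c2"]]
    sum(out^2)
  }
  fw <- pestvision:::nn_forward(net, params, x)
  out <- fw$outs[["c2"]]
  bk <- pestvision:::nn_backward(net, params, fw, list(c2 = 2 * out))
  # parameter gradients
  for (id in c("c1", "c2")) {
    for (nm in c("W", "b")) {
      num <- numeric_grad(function(v) {
        p2 <- params; p2[[id]][[nm]] <- v; loss_of(p2, x)
      }, params[[id]][[nm]])
      expect_equal(as.numeric(bk$param_grads[[id]][[nm]]), as.numeric(num),
                   tolerance = 1e-5)
    }
  }
  # input gradient
  numx <- numeric_grad(function(v) loss_of(params, v), x)
  expect_equal(as.numeric(bk$x_grad), as.numeric(numx), tolerance = 1e-5)
})

test_that("branching ops (concat, add, upsample, avgpool, zeropad) backprop correctly", {
  net <- pestvision:::nn_network(list(
    pestvision:::nn_node("in", "input"),
    pestvision:::nn_node("pad", "zeropad", "in", p = 1L),
    pestvision:::nn_node("c1", "conv", "pad", k = 3L, pad = 0L, cin = 2L, cout = 2L, act = "leaky"),
    pestvision:::nn_node("a1", "add", c("c1", "in")),
    pestvision:::nn_node("av", "avgpool", "a1", k = 2L, stride = 2L),
    pestvision:::nn_node("up", "upsample", "av", factor = 2L),
    pestvision:::nn_node("cc", "concat", c("a1", "up"))
  ), "cc")
  params <- pestvision:::nn_init_params(net, seed = 5)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  loss_of <- function(p, xx) {
    sum(sin(pestvision:::nn_forward(net, p, xx, keep_cache = FALSE)$outs[["cc"]]))
  }
  fw <- pestvision:::nn_forward(net, params, x)
  g_out <- cos(fw$outs[["cc"]])
  bk <- pestvision:::nn_backward(net, params, fw, list(cc = g_out))
  numx <- numeric_grad(function(v) loss_of(params, v), x)
  expect_equal(as.numeric(bk$x_grad), as.numeric(numx), tolerance = 1e-5)
  numW <- numeric_grad(function(v) {
    p2 <- params; p2$c1$W <- v; loss_of(p2, x)
  }, params$c1$W)
  expect_equal(as.numeric(bk$param_grads$c1$W), as.numeric(numW), tolerance = 1e-5)
})

test_that("convolution forward matches a direct sliding-window computation", {
  net <- pestvision:::nn_network(list(
    pestvision:::nn_node("in", "input"),
    pestvision:::nn_node("c", "conv", "in", k = 3L, stride = 1L, pad = 1L,
                         cin = 1L, cout = 1L, act = "linear")
  ), "c")
  params <- pestvision:::nn_init_params(net, seed = 1)
  x <- array(rnorm(25), c(5, 5, 1))
  out <- pestvision:::nn_forward(net, params, x, keep_cache = FALSE)$outs[["c"]]
  W <- params$c$W[, , 1, 1]
  direct <- matrix(0, 5, 5)
  xp <- matrix(0, 7, 7); xp[2:6, 2:6] <- x[, , 1]
  for (i in 1:5) for (j in 1:5) {
    direct[i, j] <- sum(xp[i:(i + 2), j:(j + 2)] * W) + params$c$b
  }
  expect_equal(out[, , 1], direct, tolerance = 1e-12)
})

test_that("max pooling equals a brute-force block maximum", {
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  r <- pestvision:::maxpool_cpp(x, 2L, 2L, 0L)
  for (c in 1:2) for (i in 1:4) for (j in 1:4) {
    expect_equal(r$out[i, j, c],
                 max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c]))
  }
})

test_that("ROI pooling matches per-bin enumeration and handles tiny proposals", {
  feat <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  props <- tibble::tibble(x1 = 8, y1 = 16, x2 = 40, y2 = 48)  # image coords, stride 8
  pooled <- roi_pool(feat, props, output_size = 2L, stride = 8L)
  # feature-space roi: x 1..5, y 2..6 -> bins of 2x2 cells
  for (py in 1:2) for (px in 1:2) for (c in 1:3) {
    ys <- (2 + (py - 1) * 2 + 1):(2 + py * 2)
    xs <- (1 + (px - 1) * 2 + 1):(1 + px * 2)
    expect_equal(pooled[py, px, c, 1], max(feat[ys, xs, c]))
  }
  # constant feature map: every bin equals the constant
  cf <- array(3.14, c(8, 8, 1))
  pc <- roi_pool(cf, tibble::tibble(x1 = 0, y1 = 0, x2 = 64, y2 = 64), 4L, 8L)
  expect_true(all(pc == 3.14))
  # output_size 1 on the whole map is the global max
  g <- roi_pool(feat, tibble::tibble(x1 = 0, y1 = 0, x2 = 64, y2 = 64), 1L, 8L)
  for (c in 1:3) expect_equal(g[1, 1, c, 1], max(feat[, , c]))
  # sub-cell proposal pools from its containing cell without crashing
  tiny <- roi_pool(feat, tibble::tibble(x1 = 12, y1 = 12, x2 = 13, y2 = 13), 2L, 8L)
  expect_true(all(is.finite(tiny)))
  expect_equal(as.numeric(tiny), rep(feat[2, 2, ], each = 4))
})

test_that("Adam decreases a simple quadratic objective deterministically", {
  params <- list(w = list(W = matrix(c(5, -3), 1, 2)))
  st <- pestvision:::adam_state()
  traj <- numeric(50)
  for (i in 1:50) {
    g <- list(w = list(W = 2 * params$w$W))
    upd <- pestvision:::adam_step(params, g, st, lr = 0.1)
    params <- upd$params; st <- upd$state
    traj[i] <- sum(params$w$W^2)
  }
  expect_lt(traj[50], 1)
  expect_true(all(diff(traj) <= 1e-8))
})
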