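# Minimal static-graph neural-network core.
#
# A network is a list of nodes evaluated in order; each node names its input
# node(s), so branches, concatenations and residual additions are plain
# graph edges. Tensors are (H, W, C) arrays; convolutions run through the
# C++ im2col/col2im kernels with the matrix products left to BLAS. Backward
# passes are hand-derived per op. This core exists because no autodiff stack
# is available to the package; it is deterministic given the initialization
# seed and single-threaded BLAS.

nn_node <- function(id, op, inputs = character(), ...) {
  list(id = id, op = op, inputs = inputs, cfg = list(...))
}

nn_network <- function(nodes, outputs) {
  ids <- vapply(nodes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) abort("duplicate node ids in network")
  names(nodes) <- ids
  structure(list(nodes = nodes, outputs = outputs), class = "pv_network")
}

#' @export
print.pv_network <- function(x, ...) {
  cat("<pv_network>", length(x$nodes), "nodes ->",
      paste(x$outputs, collapse = ", "), "\n")
  invisible(x)
}

# He-style initialization for every parameterized node, from a fixed seed.
nn_init_params <- function(net, seed = 1L) {
  with_seed(seed, {
    params <- list()
    for (nd in net$nodes) {
      if (nd$op == "conv") {
        k <- nd$cfg$k; cin <- nd$cfg$cin; cout <- nd$cfg$cout
        sd <- sqrt(2 / (k * k * cin))
        params[[nd$id]] <- list(
          W = array(rnorm(k * k * cin * cout, 0, sd), dim = c(k, k, cin, cout)),
          b = numeric(cout)
        )
      } else if (nd$op == "fc") {
        din <- nd$cfg$din; dout <- nd$cfg$dout
        sd <- sqrt(2 / din)
        params[[nd$id]] <- list(W = matrix(rnorm(din * dout, 0, sd), din, dout),
                                b = numeric(dout))
      } else if (nd$op == "bn") {
        d <- nd$cfg$d
        params[[nd$id]] <- list(gamma = rep(1, d), beta = numeric(d),
                                run_mean = numeric(d), run_var = rep(1, d))
      }
    }
    params
  })
}

leaky_relu <- function(x, slope = 0.1) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope = 0.1) ifelse(x > 0, 1, slope)
sigmoid <- function(x) 1 / (1 + exp(-x))

act_fwd <- function(x, act) {
  switch(act, linear = x, leaky = leaky_relu(x), relu = pmax(x, 0))
}
act_bwd <- function(pre, act) {
  switch(act, linear = 1, leaky = leaky_relu_grad(pre),
         relu = as.numeric(pre > 0))
}

# Forward pass over the whole graph for a single (H, W, C) input.
nn_forward <- function(net, params, x, keep_cache = TRUE) {
  outs <- list(); caches <- list()
  for (nd in net$nodes) {
    out <- switch(nd$op,
      input = x,
      conv = {
        inp <- outs[[nd$inputs]]
        k <- nd$cfg$k; stride <- nd$cfg$stride %||% 1L
        pad <- nd$cfg$pad %||% ((k - 1L) %/% 2L)
        cols <- im2col_cpp(inp, k, stride, pad)
        Wm <- matrix(params[[nd$id]]$W, ncol = nd$cfg$cout)
        pre <- cols %*% Wm
        pre <- sweep(pre, 2, params[[nd$id]]$b, `+`)
        d <- dim(inp)
        Ho <- (d[1] + 2 * pad - k) %/% stride + 1
        Wo <- (d[2] + 2 * pad - k) %/% stride + 1
        a <- act_fwd(pre, nd$cfg$act %||% "leaky")
        if (keep_cache) caches[[nd$id]] <- list(cols = cols, pre = pre, din = d)
        array(a, dim = c(Ho, Wo, nd$cfg$cout))
      },
      maxpool = {
        inp <- outs[[nd$inputs]]
        r <- maxpool_cpp(inp, nd$cfg$k, nd$cfg$stride,
                         nd$cfg$pad %||% ((nd$cfg$k - 1L) %/% 2L))
        if (keep_cache) caches[[nd$id]] <- list(idx = r$idx, din = dim(inp))
        r$out
      },
      avgpool = {
        inp <- outs[[nd$inputs]]
        k <- nd$cfg$k; s <- nd$cfg$stride
        d <- dim(inp)
        Ho <- d[1] %/% s; Wo <- d[2] %/% s
        cols <- im2col_cpp(inp, k, s, 0L)
        # average each k*k block per channel
        out <- array(0, dim = c(Ho, Wo, d[3]))
        for (c in seq_len(d[3])) {
          blk <- cols[, ((c - 1) * k * k + 1):(c * k * k), drop = FALSE]
          out[, , c] <- matrix(rowMeans(blk), Ho, Wo)
        }
        if (keep_cache) caches[[nd$id]] <- list(din = d)
        out
      },
      upsample = {
        inp <- outs[[nd$inputs]]
        f <- nd$cfg$factor
        d <- dim(inp)
        inp[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), , drop = FALSE]
      },
      concat = {
        parts <- lapply(nd$inputs, function(i) outs[[i]])
        if (keep_cache) caches[[nd$id]] <- vapply(parts, function(p) dim(p)[3], numeric(1))
        array(c(do.call(abind3, parts)), dim = c(dim(parts[[1]])[1:2],
                                                 sum(vapply(parts, function(p) dim(p)[3], numeric(1)))))
      },
      add = outs[[nd$inputs[1]]] + outs[[nd$inputs[2]]],
      zeropad = {
        inp <- outs[[nd$inputs]]
        p <- nd$cfg$p
        d <- dim(inp)
        out <- array(0, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
        out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- inp
        if (keep_cache) caches[[nd$id]] <- list(din = d)
        out
      },
      identity = outs[[nd$inputs]],
      abort(paste("unknown op", nd$op))
    )
    outs[[nd$id]] <- out
  }
  list(outs = outs, caches = caches)
}

abind3 <- function(...) {
  parts <- list(...)
  d12 <- dim(parts[[1]])[1:2]
  array(unlist(lapply(parts, as.vector)), dim = c(d12, sum(vapply(parts, function(p) dim(p)[3], numeric(1)))))
}

# Backward pass: out_grads is a named list (node id -> gradient array).
# Returns param gradients (same shapes as params) and the input gradient.
nn_backward <- function(net, params, fw, out_grads) {
  grads <- out_grads
  pgrads <- list()
  x_grad <- NULL
  add_grad <- function(id, g) {
    if (is.null(grads[[id]])) grads[[id]] <<- g else grads[[id]] <<- grads[[id]] + g
  }
  for (nd in rev(net$nodes)) {
    g <- grads[[nd$id]]
    if (is.null(g)) next
    switch(nd$op,
      input = { x_grad <- if (is.null(x_grad)) g else x_grad + g },
      conv = {
        cache <- fw$caches[[nd$id]]
        k <- nd$cfg$k; stride <- nd$cfg$stride %||% 1L
        pad <- nd$cfg$pad %||% ((k - 1L) %/% 2L)
        cout <- nd$cfg$cout
        gm <- matrix(g, ncol = cout)
        dpre <- gm * act_bwd(cache$pre, nd$cfg$act %||% "leaky")
        pg <- list(
          W = array(crossprod(cache$cols, dpre), dim = dim(params[[nd$id]]$W)),
          b = colSums(dpre)
        )
        if (is.null(pgrads[[nd$id]])) pgrads[[nd$id]] <- pg
        else pgrads[[nd$id]] <- list(W = pgrads[[nd$id]]$W + pg$W,
                                     b = pgrads[[nd$id]]$b + pg$b)
        Wm <- matrix(params[[nd$id]]$W, ncol = cout)
        dcols <- dpre %*% t(Wm)
        din <- cache$din
        add_grad(nd$inputs, col2im_cpp(dcols, din[1], din[2], din[3], k, stride, pad))
      },
      maxpool = {
        cache <- fw$caches[[nd$id]]
        add_grad(nd$inputs, maxpool_bwd_cpp(as.numeric(g), cache$idx,
                                            cache$din[1], cache$din[2], cache$din[3]))
      },
      avgpool = {
        cache <- fw$caches[[nd$id]]
        k <- nd$cfg$k; s <- nd$cfg$stride
        din <- cache$din
        Ho <- din[1] %/% s; Wo <- din[2] %/% s
        dx <- array(0, dim = din)
        gk <- g / (k * k)
        # distribute each bin's mean-gradient over its k x k block
        for (dh in 0:(k - 1)) for (dw in 0:(k - 1)) {
          hs <- seq_len(Ho) * s - s + 1 + dh
          ws <- seq_len(Wo) * s - s + 1 + dw
          ok_h <- hs <= din[1]; ok_w <- ws <= din[2]
          dx[hs[ok_h], ws[ok_w], ] <- dx[hs[ok_h], ws[ok_w], , drop = FALSE] +
            gk[ok_h, ok_w, , drop = FALSE]
        }
        add_grad(nd$inputs, dx)
      },
      upsample = {
        f <- nd$cfg$factor
        d <- dim(g)
        Hs <- d[1] %/% f; Ws <- d[2] %/% f
        dx <- array(0, dim = c(Hs, Ws, d[3]))
        for (dh in 1:f) for (dw in 1:f) {
          dx <- dx + g[seq(dh, d[1], by = f), seq(dw, d[2], by = f), , drop = FALSE]
        }
        add_grad(nd$inputs, dx)
      },
      concat = {
        chans <- fw$caches[[nd$id]]
        start <- 0
        for (i in seq_along(nd$inputs)) {
          add_grad(nd$inputs[i], g[, , (start + 1):(start + chans[i]), drop = FALSE])
          start <- start + chans[i]
        }
      },
      add = {
        add_grad(nd$inputs[1], g)
        add_grad(nd$inputs[2], g)
      },
      zeropad = {
        p <- nd$cfg$p
        din <- fw$caches[[nd$id]]$din
        add_grad(nd$inputs, g[(p + 1):(p + din[1]), (p + 1):(p + din[2]), , drop = FALSE])
      },
      identity = add_grad(nd$inputs, g)
    )
  }
  list(param_grads = pgrads, x_grad = x_grad)
}

# Count learnable parameters. include_bias = FALSE counts convolution kernel
# weights only, the convention of the bottleneck-savings arithmetic.
nn_count_params <- function(net, include_bias = TRUE, ids = NULL) {
  total <- 0
  for (nd in net$nodes) {
    if (!is.null(ids) && !(nd$id %in% ids)) next
    if (nd$op == "conv") {
      total <- total + nd$cfg$k^2 * nd$cfg$cin * nd$cfg$cout +
        if (include_bias) nd$cfg$cout else 0
    } else if (nd$op == "fc") {
      total <- total + nd$cfg$din * nd$cfg$dout + if (include_bias) nd$cfg$dout else 0
    } else if (nd$op == "bn") {
      total <- total + 2 * nd$cfg$d
    }
  }
  total
}

# --- Adam optimizer ---------------------------------------------------------

adam_state <- function() list(m = list(), v = list(), t = 0)

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  for (id in names(grads)) {
    for (nm in names(grads[[id]])) {
      g <- grads[[id]][[nm]]
      key <- paste0(id, ".", nm)
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g * 0
        state$v[[key]] <- g * 0
      }
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
      mhat <- state$m[[key]] / (1 - beta1^t)
      vhat <- state$v[[key]] / (1 - beta2^t)
      params[[id]][[nm]] <- params[[id]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

# Scale accumulated gradients (e.g. average over a minibatch).
scale_grads <- function(grads, f) {
  lapply(grads, function(p) lapply(p, function(g) g * f))
}

sum_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (id in names(b)) {
    if (is.null(a[[id]])) a[[id]] <- b[[id]]
    else for (nm in names(b[[id]])) a[[id]][[nm]] <- a[[id]][[nm]] + b[[id]][[nm]]
  }
  a
}
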