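#' Specify the transfer-learning classifier head
#'
#' The foliar-disease images need only classification, not detection. The
#' classifier pads the input with a 2-pixel zero border (edge information is
#' preserved and the feature-map size controlled), runs a convolutional
#' stack whose weights may be transferred from a pretrained backbone (and
#' remain trainable), then a 2x2 average pool, a flatten, a 1024-wide
#' fully-connected layer with ReLU, one batch-normalization layer, and a
#' final fully-connected layer with softmax scores over the classes.
#'
#' @param num_classes number of disease classes (>= 2).
#' @param input_size square input side (default 32 at desk scale).
#' @param pad zero-padding width (2).
#' @param pool average-pool window (2).
#' @param fc1_dim width of the first fully-connected layer (1024).
#' @param batch_norm_between_fc keep the normalization layer between the two
#'   fully-connected layers.
#' @param conv_widths channel widths of the three stride-2 conv layers.
#' @return A `classifier_head_spec`.
#' @export
classifier_head_spec <- function(num_classes, input_size = 32, pad = 2L,
                                 pool = 2L, fc1_dim = 1024L,
                                 batch_norm_between_fc = TRUE,
                                 conv_widths = c(8L, 16L, 32L)) {
  if (num_classes < 2) abort("num_classes must be >= 2")
  structure(list(num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size), pad = as.integer(pad),
                 pool = as.integer(pool), fc1_dim = as.integer(fc1_dim),
                 batch_norm_between_fc = batch_norm_between_fc,
                 conv_widths = as.integer(conv_widths)),
            class = "classifier_head_spec")
}

#' Build the disease classifier
#'
#' Assembles zero-pad, conv stack, average pool, flatten and the
#' fully-connected head. `backbone_params` transfers convolutional weights
#' (they stay trainable); shapes must match the spec's conv widths.
#'
#' @param spec a [classifier_head_spec()].
#' @param backbone_params optional named list of conv params (`conv1` ..)
#'   to transfer.
#' @param seed initialization seed.
#' @return A `pv_classifier` with `$network` (conv part), `$head`
#'   (fc1/bn/fc2 parameters), `$spec`, and a `$layers` inventory tibble.
#' @export
build_classifier <- function(spec, backbone_params = NULL, seed = 1L) {
  w <- spec$conv_widths
  nodes <- list(
    nn_node("in", "input"),
    nn_node("padded", "zeropad", "in", p = spec$pad),
    nn_node("conv1", "conv", "padded", k = 3L, stride = 2L, pad = 1L,
            cin = 3L, cout = w[1], act = "relu"),
    nn_node("conv2", "conv", "conv1", k = 3L, stride = 2L, pad = 1L,
            cin = w[1], cout = w[2], act = "relu"),
    nn_node("conv3", "conv", "conv2", k = 3L, stride = 2L, pad = 1L,
            cin = w[2], cout = w[3], act = "relu"),
    nn_node("pooled", "avgpool", "conv3", k = spec$pool, stride = spec$pool)
  )
  net <- nn_network(nodes, "pooled")
  params <- nn_init_params(net, seed)
  if (!is.null(backbone_params)) {
    for (id in names(backbone_params)) {
      if (!id %in% names(params)) abort(paste0("no conv layer '", id, "' to transfer into"))
      if (!identical(dim(params[[id]]$W), dim(backbone_params[[id]]$W))) {
        abort(paste0("transferred weights for '", id, "' have mismatched shape"))
      }
      params[[id]] <- backbone_params[[id]]
    }
  }
  side <- spec$input_size + 2 * spec$pad
  for (i in 1:3) side <- (side + 2 - 3) %/% 2 + 1
  side <- side %/% spec$pool
  din <- side^2 * w[3]
  head <- with_seed(derive_seed(seed, 23L), list(
    fc1 = list(W = matrix(rnorm(din * spec$fc1_dim, 0, sqrt(2 / din)),
                          din, spec$fc1_dim), b = numeric(spec$fc1_dim)),
    bn = list(gamma = rep(1, spec$fc1_dim), beta = numeric(spec$fc1_dim),
              run_mean = numeric(spec$fc1_dim), run_var = rep(1, spec$fc1_dim)),
    fc2 = list(W = matrix(rnorm(spec$fc1_dim * spec$num_classes, 0,
                                sqrt(2 / spec$fc1_dim)),
                          spec$fc1_dim, spec$num_classes),
               b = numeric(spec$num_classes))
  ))
  layers <- tibble(
    layer = c("zeropad", "conv1", "conv2", "conv3", "avgpool", "flatten",
              "fc1", "relu",
              if (spec$batch_norm_between_fc) "batch_norm" else NULL,
              "fc2", "softmax"),
    kind = c("pad", "conv", "conv", "conv", "pool", "reshape",
             "fully_connected", "activation",
             if (spec$batch_norm_between_fc) "normalization" else NULL,
             "fully_connected", "activation")
  )
  structure(list(network = net, params = params, head = head, spec = spec,
                 feature_dim = din, layers = layers),
            class = "pv_classifier")
}

# Conv-stack features for a batch of images -> N x feature_dim matrix.
classifier_features <- function(model, images, keep_cache = FALSE) {
  feats <- matrix(0, length(images), model$feature_dim)
  fws <- if (keep_cache) vector("list", length(images)) else NULL
  for (i in seq_along(images)) {
    fw <- nn_forward(model$network, model$params, images[[i]], keep_cache = keep_cache)
    feats[i, ] <- as.numeric(fw$outs[["pooled"]])
    if (keep_cache) fws[[i]] <- fw
  }
  list(feats = feats, fws = fws)
}

# Head forward: fc1 -> ReLU -> batch norm -> fc2 -> softmax. In inference
# mode the BN running statistics are used, so single images are fine.
classifier_head_forward <- function(model, feats, train = FALSE, bn_momentum = 0.9) {
  h <- model$head
  z1 <- sweep(feats %*% h$fc1$W, 2, h$fc1$b, `+`)
  a1 <- pmax(z1, 0)
  if (model$spec$batch_norm_between_fc) {
    if (train) {
      mu <- colMeans(a1)
      v <- colMeans(sweep(a1, 2, mu)^2)
    } else {
      mu <- h$bn$run_mean; v <- h$bn$run_var
    }
    xhat <- sweep(sweep(a1, 2, mu), 2, sqrt(v + 1e-5), `/`)
    bn_out <- sweep(sweep(xhat, 2, h$bn$gamma, `*`), 2, h$bn$beta, `+`)
  } else {
    mu <- NULL; v <- NULL; xhat <- NULL; bn_out <- a1
  }
  logits <- sweep(bn_out %*% h$fc2$W, 2, h$fc2$b, `+`)
  list(z1 = z1, a1 = a1, mu = mu, v = v, xhat = xhat, bn_out = bn_out,
       logits = logits, probs = softmax_rows(logits))
}

#' Classify an image
#'
#' @param model a `pv_classifier`.
#' @param image `H x W x 3` 8-bit array at the spec's input size.
#' @return Named numeric vector of class scores (non-negative, summing to 1).
#' @param class_names optional labels.
#' @export
classify <- function(model, image, class_names = NULL) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) abort("expected an H x W x 3 image")
  f <- classifier_features(model, list(normalize_image(image)))
  hf <- classifier_head_forward(model, f$feats, train = FALSE)
  p <- hf$probs[1, ]
  names(p) <- class_names %||% paste0("class_", seq_along(p) - 1)
  p
}
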