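#' Training configuration
#'
#' Adam with an initial learning rate of 1e-4 is the reference optimizer
#' setting; the schedule is cosine decay from that rate. The dataset is
#' split 7:3 train/test by default. All randomness (split, shuffling,
#' augmentation, initialization) derives from `seed`.
#'
#' @param model `"inc_yolo"`, `"cluster_rcnn"` or `"classifier"`.
#' @param epochs,batch_size loop sizes.
#' @param lr initial Adam learning rate (default 1e-4).
#' @param split train fraction (default 0.7).
#' @param seed master seed.
#' @param augment logical: apply online augmentation while training.
#' @param augment_opts arguments passed to [augment_params()].
#' @param freeze_backbone classifier only: do not update transferred conv
#'   weights.
#' @param eval_every evaluate validation metric every this many epochs.
#' @param conf_thresh detection confidence floor used for validation mAP.
#' @param lr_schedule `"cosine"` or `"constant"`.
#' @return A `train_config` list.
#' @export
train_config <- function(model = c("inc_yolo", "cluster_rcnn", "classifier"),
                         epochs = 10L, batch_size = 8L, lr = 1e-4, split = 0.7,
                         seed = 1L, augment = TRUE, augment_opts = list(),
                         freeze_backbone = FALSE, eval_every = NULL,
                         conf_thresh = 0.1, lr_schedule = c("cosine", "constant")) {
  model <- match.arg(model)
  lr_schedule <- match.arg(lr_schedule)
  if (lr <= 0) abort("learning rate must be positive")
  if (split <= 0 || split >= 1) abort("split must be in (0, 1)")
  structure(list(model = model, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr, split = split,
                 seed = as.integer(seed), augment = augment,
                 augment_opts = augment_opts, freeze_backbone = freeze_backbone,
                 eval_every = eval_every %||% max(1L, as.integer(epochs)),
                 conf_thresh = conf_thresh, lr_schedule = lr_schedule),
            class = "train_config")
}

lr_at <- function(config, epoch) {
  if (config$lr_schedule == "constant") return(config$lr)
  config$lr * 0.5 * (1 + cos(pi * (epoch - 1) / max(config$epochs, 1)))
}

#' Train a model on a manifest
#'
#' Splits the manifest ([split_dataset()]), runs the online-augmented
#' minibatch fit loop for the configured model, logs per-epoch loss and the
#' validation metric (mAP for detectors, accuracy for the classifier) and
#' keeps the best-metric parameters. Fully seeded: identical config and
#' seed give identical logs.
#'
#' @param config a [train_config()].
#' @param manifest a rendered manifest (images in the `image` list-column).
#' @param model optionally a pre-built model (else one is built from
#'   `model_args`).
#' @param model_args arguments for [inc_yolo_spec()] /
#'   [cluster_rcnn_spec()] / [classifier_head_spec()] when `model` is NULL.
#' @return A `pv_fit`: list with `model`, `history` tibble, `config`,
#'   `class_names`, `val` manifest and the final validation `metric`.
#' @export
train <- function(config, manifest, model = NULL, model_args = list()) {
  class_names <- sort(unique(unlist(purrr::map(manifest$boxes, "class_name"))))
  parts <- split_dataset(manifest, config$split, derive_seed(config$seed, 1L))
  fit <- switch(config$model,
    inc_yolo = train_inc_yolo(config, parts$train, parts$test, model, model_args, class_names),
    cluster_rcnn = train_cluster_rcnn(config, parts$train, parts$test, model, model_args, class_names),
    classifier = train_classifier(config, parts$train, parts$test, model, model_args, class_names)
  )
  fit$config <- config
  fit$class_names <- class_names
  fit$log_header <- list(optimizer = "adam", initial_lr = config$lr,
                         epochs = config$epochs, seed = config$seed,
                         split = config$split)
  structure(fit, class = "pv_fit")
}

#' @export
print.pv_fit <- function(x, ...) {
  cat("<pv_fit>", x$config$model, "-", nrow(x$history), "epochs, final metric",
      round(utils::tail(x$history$metric[!is.na(x$history$metric)], 1), 4), "\n")
  invisible(x)
}

#' @export
tidy.pv_fit <- function(x, ...) x$history

#' @export
glance.pv_fit <- function(x, ...) {
  tibble(model = x$config$model, epochs = x$config$epochs,
         final_loss = utils::tail(x$history$loss, 1),
         metric = utils::tail(x$history$metric[!is.na(x$history$metric)], 1))
}

#' Plot a training history
#'
#' @param object a `pv_fit`.
#' @param ... unused.
#' @return A ggplot of loss (and validation metric) against epoch.
#' @export
autoplot.pv_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("loss", "metric"),
                           names_to = "series", values_to = "value")
  h <- h[!is.na(h$value), ]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::theme_minimal()
}

maybe_augment <- function(image, boxes, config, seed) {
  if (!config$augment) return(list(image = image, boxes = boxes))
  p <- do.call(augment_params, c(list(seed = seed), config$augment_opts))
  res <- apply_augmentation(image, boxes, p)
  if (nrow(boxes) > 0 && nrow(res$boxes) == 0) {
    return(list(image = image, boxes = boxes))  # keep label signal
  }
  res
}

train_inc_yolo <- function(config, train_man, val_man, model, model_args, class_names) {
  if (is.null(model)) {
    args <- utils::modifyList(list(num_classes = length(class_names),
                                   input_size = train_man$width[1]), model_args)
    model <- build_inc_yolo(do.call(inc_yolo_spec, args),
                            seed = derive_seed(config$seed, 2L))
  }
  st <- adam_state()
  history <- list()
  best <- list(metric = -Inf, params = model$params)
  step_seed <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, 100L + epoch),
                     sample.int(nrow(train_man)))
    epoch_loss <- 0
    batch_grads <- NULL; batch_n <- 0
    for (ii in ord) {
      step_seed <- step_seed + 1L
      aug <- maybe_augment(train_man$image[[ii]], train_man$boxes[[ii]],
                           config, derive_seed(config$seed, 7000L + step_seed))
      x <- normalize_image(aug$image)
      fwd <- inc_yolo_forward(model, x, keep_cache = TRUE)
      tg <- encode_targets(aug$boxes, model$spec)
      ls <- yolo_loss(fwd$maps, tg, model$spec)
      epoch_loss <- epoch_loss + ls$total
      bk <- nn_backward(model$network, model$params, fwd$fw, ls$grads)
      batch_grads <- sum_grads(batch_grads, bk$param_grads)
      batch_n <- batch_n + 1
      if (batch_n == config$batch_size || ii == ord[length(ord)]) {
        upd <- adam_step(model$params, scale_grads(batch_grads, 1 / batch_n),
                         st, lr = lr_at(config, epoch))
        model$params <- upd$params; st <- upd$state
        batch_grads <- NULL; batch_n <- 0
      }
    }
    mean_loss <- epoch_loss / nrow(train_man)
    if (!is.finite(mean_loss)) abort("divergent loss (NaN) while training inc-YOLO")
    metric <- NA_real_
    if (epoch %% config$eval_every == 0 || epoch == config$epochs) {
      metric <- detector_val_map(function(img) {
        inc_yolo_detect(model, img, conf_thresh = config$conf_thresh,
                        class_names = class_names)
      }, val_man)
      if (metric >= best$metric) best <- list(metric = metric, params = model$params)
    }
    history[[epoch]] <- tibble(epoch = epoch, loss = mean_loss, metric = metric)
  }
  model$params <- best$params
  list(model = model, history = dplyr::bind_rows(history), metric = best$metric,
       val = val_man)
}

detector_val_map <- function(detect_fn, val_man) {
  dets <- purrr::map_dfr(seq_len(nrow(val_man)), function(i) {
    d <- detect_fn(val_man$image[[i]])
    if (nrow(d)) d$image_id <- val_man$image_id[i]
    d
  })
  if (!nrow(dets)) return(0)
  evaluate_detections(dets, val_man)$map
}

smooth_l1 <- function(x) ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)
smooth_l1_grad <- function(x) ifelse(abs(x) < 1, x, sign(x))

train_cluster_rcnn <- function(config, train_man, val_man, model, model_args, class_names) {
  if (is.null(model)) {
    args <- utils::modifyList(list(num_classes = length(class_names),
                                   input_size = train_man$width[1]), model_args)
    if (is.null(args$anchors)) {
      pop <- box_population(train_man)
      k <- min(6L, max(2L, nrow(dplyr::distinct(pop))))
      args$anchors <- as_anchor_set(kmeans_iou(pop, k, seed = derive_seed(config$seed, 3L)))
    }
    model <- build_cluster_rcnn(do.call(cluster_rcnn_spec, args),
                                seed = derive_seed(config$seed, 4L))
  }
  spec <- model$spec
  cfg <- spec$config
  st <- adam_state(); st_head <- adam_state()
  history <- list()
  best <- list(metric = -Inf, params = model$params, head = model$head)
  step_seed <- 0L
  anchors_cache <- NULL
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, 200L + epoch),
                     sample.int(nrow(train_man)))
    epoch_loss <- 0
    for (ii in ord) {
      step_seed <- step_seed + 1L
      aug <- maybe_augment(train_man$image[[ii]], train_man$boxes[[ii]],
                           config, derive_seed(config$seed, 9000L + step_seed))
      x <- normalize_image(aug$image)
      gt <- aug$boxes
      cv <- rcnn_conv_forward(model, x, keep_cache = TRUE)
      if (is.null(anchors_cache)) {
        anchors_cache <- generate_anchors(cv$feature_h, cv$feature_w, cfg)
      }
      anchors <- anchors_cache
      lab <- label_anchors(anchors, gt, cfg)
      res <- with_seed(derive_seed(config$seed, 5000L + step_seed), {
        rcnn_losses(model, cv, anchors, lab, gt, spec, cfg)
      })
      epoch_loss <- epoch_loss + res$loss
      if (!is.finite(res$loss)) abort("divergent loss (NaN) while training cluster-RCNN")
      bk <- nn_backward(model$network, model$params, cv$fw, res$out_grads)
      upd <- adam_step(model$params, bk$param_grads, st, lr = lr_at(config, epoch))
      model$params <- upd$params; st <- upd$state
      updh <- adam_step(model$head, res$head_grads, st_head, lr = lr_at(config, epoch))
      model$head <- updh$params; st_head <- updh$state
    }
    mean_loss <- epoch_loss / nrow(train_man)
    metric <- NA_real_
    if (epoch %% config$eval_every == 0 || epoch == config$epochs) {
      metric <- detector_val_map(function(img) {
        cluster_rcnn_detect(model, img, score_thresh = config$conf_thresh,
                            class_names = class_names,
                            proposal_budget = c(300L, 50L))
      }, val_man)
      if (metric >= best$metric) {
        best <- list(metric = metric, params = model$params, head = model$head)
      }
    }
    history[[epoch]] <- tibble(epoch = epoch, loss = mean_loss, metric = metric)
  }
  model$params <- best$params; model$head <- best$head
  list(model = model, history = dplyr::bind_rows(history), metric = best$metric,
       val = val_man)
}

# One image's RPN + head losses and gradients for the two-stage detector.
rcnn_losses <- function(model, cv, anchors, lab, gt, spec, cfg,
                        rpn_batch = 32L, roi_batch = 16L) {
  K <- nrow(spec$anchors)
  S_h <- cv$feature_h; S_w <- cv$feature_w
  loss <- 0
  # --- RPN objectness + regression on a sampled anchor minibatch
  pos_idx <- which(lab$labels == "pos")
  neg_idx <- which(lab$labels == "neg")
  n_pos <- min(length(pos_idx), rpn_batch %/% 2L)
  sel_pos <- if (n_pos) pos_idx[sample.int(length(pos_idx), n_pos)] else integer(0)
  n_neg <- min(length(neg_idx), rpn_batch - n_pos)
  sel_neg <- if (n_neg) neg_idx[sample.int(length(neg_idx), n_neg)] else integer(0)
  g_obj_flat <- numeric(length(cv$objectness))
  g_del_flat <- matrix(0, nrow(cv$deltas), 4)
  sel <- c(sel_pos, sel_neg)
  if (length(sel)) {
    t_obj <- as.numeric(seq_along(sel) <= n_pos)
    bo <- bce_sig(cv$objectness[sel], t_obj)
    loss <- loss + sum(bo$loss) / length(sel)
    g_obj_flat[sel] <- bo$grad / length(sel)
  }
  if (length(sel_pos)) {
    diffs <- cv$deltas[sel_pos, , drop = FALSE] - lab$targets[sel_pos, , drop = FALSE]
    loss <- loss + sum(smooth_l1(diffs)) / length(sel_pos)
    g_del_flat[sel_pos, ] <- smooth_l1_grad(diffs) / length(sel_pos)
  }
  # scatter flat anchor-order grads back into map layout (k, x, y)
  g_obj_map <- aperm(array(g_obj_flat, dim = c(K, S_w, S_h)), c(3, 2, 1))
  g_del_map <- array(0, dim = c(S_h, S_w, 4 * K))
  for (d in 1:4) {
    g_del_map[, , (seq_len(K) - 1) * 4 + d] <-
      aperm(array(g_del_flat[, d], dim = c(K, S_w, S_h)), c(3, 2, 1))
  }
  # --- ROI head on proposals + ground-truth boxes
  train_cfg <- cfg; train_cfg$pre_nms_top_n <- 300L; train_cfg$post_nms_top_n <- 30L
  props <- propose(sigmoid(cv$objectness), cv$deltas, anchors, train_cfg, spec$input_size)
  rois <- dplyr::bind_rows(props[, c("x1", "y1", "x2", "y2")],
                           gt[, c("x1", "y1", "x2", "y2")])
  rois <- rois[rois$x2 - rois$x1 >= 2 & rois$y2 - rois$y1 >= 2, ]
  feat_grad <- array(0, dim = dim(cv$feature))
  head_grads <- lapply(model$head, function(p) lapply(p, function(v) v * 0))
  if (nrow(rois) && nrow(gt)) {
    m <- iou_matrix_cpp(as.matrix(rois), as.matrix(gt[, c("x1", "y1", "x2", "y2")]))
    best_iou <- apply(m, 1, max)
    best_gt <- max.col(m, ties.method = "first")
    fg <- which(best_iou >= 0.5)
    bg <- which(best_iou < 0.5)
    n_fg <- min(length(fg), roi_batch %/% 2L)
    sel_fg <- if (n_fg) fg[sample.int(length(fg), n_fg)] else integer(0)
    n_bg <- min(length(bg), roi_batch - n_fg)
    sel_bg <- if (n_bg) bg[sample.int(length(bg), n_bg)] else integer(0)
    sel_roi <- c(sel_fg, sel_bg)
    if (length(sel_roi)) {
      r <- rois[sel_roi, ]
      pooled <- roi_pool(cv$feature, r, spec$roi_size, cfg$feature_stride)
      pm <- pooled_to_matrix(pooled)
      hf <- rcnn_head_forward(model$head, pm)
      probs <- softmax_rows(hf$cls_logit)
      # labels: foreground class for fg rois, background (last) for bg
      ylab <- integer(length(sel_roi))
      ylab[seq_along(sel_fg)] <- gt$class_id[best_gt[sel_fg]] + 1L
      ylab[ylab == 0L] <- spec$num_classes + 1L
      onehot <- matrix(0, length(sel_roi), spec$num_classes + 1L)
      onehot[cbind(seq_along(ylab), ylab)] <- 1
      loss <- loss + -sum(log(probs[cbind(seq_along(ylab), ylab)] + 1e-9)) / length(ylab)
      d_logit <- (probs - onehot) / length(ylab)
      # bbox regression targets for fg rois (class-agnostic)
      d_bbox <- matrix(0, length(sel_roi), 4)
      if (length(sel_fg)) {
        rb <- r[seq_along(sel_fg), ]
        gb <- gt[best_gt[sel_fg], ]
        rw <- rb$x2 - rb$x1; rh <- rb$y2 - rb$y1
        tmat <- cbind(((gb$x1 + gb$x2) / 2 - (rb$x1 + rb$x2) / 2) / rw,
                      ((gb$y1 + gb$y2) / 2 - (rb$y1 + rb$y2) / 2) / rh,
                      log((gb$x2 - gb$x1) / rw), log((gb$y2 - gb$y1) / rh))
        dif <- hf$bbox[seq_along(sel_fg), , drop = FALSE] - tmat
        loss <- loss + sum(smooth_l1(dif)) / length(sel_fg)
        d_bbox[seq_along(sel_fg), ] <- smooth_l1_grad(dif) / length(sel_fg)
      }
      # backprop through the head
      head_grads$cls$W <- crossprod(hf$a1, d_logit)
      head_grads$cls$b <- colSums(d_logit)
      head_grads$bbox$W <- crossprod(hf$a1, d_bbox)
      head_grads$bbox$b <- colSums(d_bbox)
      d_a1 <- d_logit %*% t(model$head$cls$W) + d_bbox %*% t(model$head$bbox$W)
      d_z1 <- d_a1 * (hf$z1 > 0)
      head_grads$fc1$W <- crossprod(pm, d_z1)
      head_grads$fc1$b <- colSums(d_z1)
      d_pm <- d_z1 %*% t(model$head$fc1$W)
      fg_grad <- roipool_bwd_cpp(as.numeric(t(d_pm)), attr(pooled, "idx"),
                                 dim(cv$feature)[1], dim(cv$feature)[2],
                                 dim(cv$feature)[3])
      feat_grad <- feat_grad + fg_grad
    }
  }
  out_grads <- list()
  out_grads[["rpn_obj"]] <- g_obj_map
  out_grads[["rpn_delta"]] <- g_del_map
  out_grads[[model$feature_id]] <- feat_grad
  list(loss = loss, out_grads = out_grads, head_grads = head_grads)
}

train_classifier <- function(config, train_man, val_man, model, model_args, class_names) {
  if (is.null(model)) {
    args <- utils::modifyList(list(num_classes = length(class_names),
                                   input_size = train_man$width[1]), model_args)
    model <- build_classifier(do.call(classifier_head_spec, args),
                              seed = derive_seed(config$seed, 5L))
  }
  label_of <- function(b) b$class_id[1] + 1L
  y_train <- vapply(train_man$boxes, label_of, integer(1))
  st <- adam_state(); st_head <- adam_state()
  history <- list()
  best <- list(metric = -Inf, params = model$params, head = model$head)
  nc <- model$spec$num_classes
  step_seed <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, 300L + epoch),
                     sample.int(nrow(train_man)))
    epoch_loss <- 0
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bt in batches) {
      step_seed <- step_seed + 1L
      imgs <- lapply(seq_along(bt), function(j) {
        aug <- maybe_augment(train_man$image[[bt[j]]], empty_boxes(), config,
                             derive_seed(config$seed, 11000L + step_seed * 100L + j))
        normalize_image(aug$image)
      })
      fx <- classifier_features(model, imgs, keep_cache = TRUE)
      hf <- classifier_head_forward(model, fx$feats, train = TRUE)
      y <- y_train[bt]
      onehot <- matrix(0, length(bt), nc)
      onehot[cbind(seq_along(y), y)] <- 1
      loss <- -sum(log(hf$probs[cbind(seq_along(y), y)] + 1e-9)) / length(y)
      epoch_loss <- epoch_loss + loss * length(bt)
      gr <- classifier_head_backward(model, fx$feats, hf, onehot)
      # update BN running stats
      if (model$spec$batch_norm_between_fc) {
        mom <- 0.9
        model$head$bn$run_mean <- mom * model$head$bn$run_mean + (1 - mom) * hf$mu
        model$head$bn$run_var <- mom * model$head$bn$run_var + (1 - mom) * hf$v
      }
      updh <- adam_step(model$head, gr$head_grads, st_head, lr = lr_at(config, epoch))
      # keep BN running stats out of the optimizer's reach
      updh$params$bn$run_mean <- model$head$bn$run_mean
      updh$params$bn$run_var <- model$head$bn$run_var
      model$head <- updh$params; st_head <- updh$state
      if (!config$freeze_backbone) {
        conv_grads <- NULL
        for (j in seq_along(bt)) {
          g_feat <- array(gr$d_feats[j, ], dim = dim(fx$fws[[j]]$outs[["pooled"]]))
          bk <- nn_backward(model$network, model$params, fx$fws[[j]],
                            list(pooled = g_feat))
          conv_grads <- sum_grads(conv_grads, bk$param_grads)
        }
        upd <- adam_step(model$params, scale_grads(conv_grads, 1 / length(bt)),
                         st, lr = lr_at(config, epoch))
        model$params <- upd$params; st <- upd$state
      }
    }
    mean_loss <- epoch_loss / nrow(train_man)
    if (!is.finite(mean_loss)) abort("divergent loss (NaN) while training classifier")
    metric <- NA_real_
    if (epoch %% config$eval_every == 0 || epoch == config$epochs) {
      metric <- classifier_accuracy(model, val_man, class_names)
      if (metric >= best$metric) {
        best <- list(metric = metric, params = model$params, head = model$head)
      }
    }
    history[[epoch]] <- tibble(epoch = epoch, loss = mean_loss, metric = metric)
  }
  model$params <- best$params; model$head <- best$head
  list(model = model, history = dplyr::bind_rows(history), metric = best$metric,
       val = val_man)
}

classifier_head_backward <- function(model, feats, hf, onehot) {
  n <- nrow(feats)
  h <- model$head
  d_logit <- (hf$probs - onehot) / n
  head_grads <- lapply(h, function(p) lapply(p, function(v) v * 0))
  head_grads$fc2$W <- crossprod(hf$bn_out, d_logit)
  head_grads$fc2$b <- colSums(d_logit)
  d_bn_out <- d_logit %*% t(h$fc2$W)
  if (model$spec$batch_norm_between_fc) {
    inv_sd <- 1 / sqrt(hf$v + 1e-5)
    head_grads$bn$gamma <- colSums(d_bn_out * hf$xhat)
    head_grads$bn$beta <- colSums(d_bn_out)
    d_xhat <- sweep(d_bn_out, 2, h$bn$gamma, `*`)
    # batch-norm backward over the batch dimension
    s1 <- colMeans(d_xhat)
    s2 <- colMeans(d_xhat * hf$xhat)
    d_a1 <- sweep(
      d_xhat - matrix(s1, n, length(s1), byrow = TRUE) -
        hf$xhat * matrix(s2, n, length(s2), byrow = TRUE),
      2, inv_sd, `*`)
  } else {
    d_a1 <- d_bn_out
  }
  d_z1 <- d_a1 * (hf$z1 > 0)
  head_grads$fc1$W <- crossprod(feats, d_z1)
  head_grads$fc1$b <- colSums(d_z1)
  d_feats <- d_z1 %*% t(h$fc1$W)
  list(head_grads = head_grads, d_feats = d_feats)
}

classifier_accuracy <- function(model, val_man, class_names) {
  y <- vapply(val_man$boxes, function(b) b$class_id[1] + 1L, integer(1))
  pred <- vapply(seq_len(nrow(val_man)), function(i) {
    which.max(classify(model, val_man$image[[i]], class_names))
  }, integer(1))
  mean(pred == y)
}

#' Save / load model checkpoints
#'
#' Checkpoints are single RDS files holding the model object (network
#' definition, parameters, spec); loading one reproduces the saved
#' validation metric exactly.
#'
#' @param model any pestvision model or `pv_fit`.
#' @param path file path.
#' @return `load_checkpoint()` returns the saved object.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Weak-class improvement recipes
#'
#' Given an imbalanced dataset with a weak (undersampled, small-object)
#' class, compares the baseline detector against three remedies: refitting
#' anchors with extra centroids clustered on the weak class's own box sizes
#' (`anchor_refit`), oversampling the weak class with augmented copies to
#' close the image-count gap (`augment_boost`), and both together. Emits a
#' four-row comparison of weak-class AP and overall mAP.
#'
#' @param manifest rendered dataset manifest.
#' @param weak_class name of the weak class.
#' @param config a [train_config()] for the (one-stage) detector runs.
#' @param recipes which remedy rows to compute.
#' @param k_anchors baseline anchor count; `k_weak` extra weak-class
#'   centroids.
#' @param k_weak extra centroids clustered on the weak class.
#' @param oversample_to target image count for the weak class (default: the
#'   median class count).
#' @return A tibble with `method`, `weak_ap`, `map` rows baseline first.
#' @export
improve_weak_class <- function(manifest, weak_class, config,
                               recipes = c("anchor_refit", "augment_boost", "both"),
                               k_anchors = 6L, k_weak = 3L, oversample_to = NULL) {
  counts <- class_table(manifest)
  if (!weak_class %in% counts$class_name) abort(paste0("weak class '", weak_class, "' absent"))
  pop_all <- box_population(manifest)
  weak_rows <- vapply(manifest$boxes, function(b) any(b$class_name == weak_class), logical(1))
  pop_weak <- box_population(manifest[weak_rows, ])
  base_anchors <- as_anchor_set(kmeans_iou(pop_all, k_anchors,
                                           seed = derive_seed(config$seed, 31L)))
  refit_anchors <- anchor_set(dplyr::bind_rows(
    as_tibble(base_anchors),
    as_tibble(as_anchor_set(kmeans_iou(pop_weak, min(k_weak, nrow(pop_weak)),
                                       seed = derive_seed(config$seed, 32L))))
  ), origin = "clustered")
  oversample_to <- oversample_to %||% round(median(counts$n_images))

  boost <- function(man) {
    n_weak <- sum(vapply(man$boxes, function(b) any(b$class_name == weak_class), logical(1)))
    need <- max(0, oversample_to - n_weak)
    if (need == 0) return(man)
    weak_man <- man[vapply(man$boxes, function(b) any(b$class_name == weak_class), logical(1)), ]
    extras <- purrr::map_dfr(seq_len(need), function(j) {
      src <- weak_man[((j - 1) %% nrow(weak_man)) + 1, ]
      p <- augment_params(seed = derive_seed(config$seed, 40000L + j))
      a <- apply_augmentation(src$image[[1]], src$boxes[[1]], p)
      if (nrow(a$boxes) == 0) a <- list(image = src$image[[1]], boxes = src$boxes[[1]])
      annotated_image(paste0(src$image_id, "_aug", j), src$width, src$height,
                      a$boxes, image = a$image)
    })
    dplyr::bind_rows(man, extras)
  }

  run <- function(anchors, use_boost) {
    man <- if (use_boost) boost(manifest) else manifest
    fit <- train(config, man, model_args = list(anchors = anchors))
    ev <- evaluate_fit(fit)
    wa <- ev$per_class$ap[ev$per_class$class_name == weak_class]
    tibble(weak_ap = if (length(wa)) wa else 0, map = ev$map)
  }

  rows <- list(dplyr::mutate(run(base_anchors, FALSE), method = "baseline"))
  if ("anchor_refit" %in% recipes) {
    rows <- c(rows, list(dplyr::mutate(run(refit_anchors, FALSE), method = "anchor_refit")))
  }
  if ("augment_boost" %in% recipes) {
    rows <- c(rows, list(dplyr::mutate(run(base_anchors, TRUE), method = "augment_boost")))
  }
  if ("both" %in% recipes) {
    rows <- c(rows, list(dplyr::mutate(run(refit_anchors, TRUE), method = "both")))
  }
  dplyr::bind_rows(rows)[, c("method", "weak_ap", "map")]
}

#' Evaluate a fitted detector on its held-out split
#'
#' @param fit a `pv_fit` from [train()].
#' @param iou_thresh evaluation IoU threshold.
#' @return A `pv_eval`.
#' @export
evaluate_fit <- function(fit, iou_thresh = 0.5) {
  detect_fn <- if (fit$config$model == "inc_yolo") {
    function(img) inc_yolo_detect(fit$model, img, conf_thresh = fit$config$conf_thresh,
                                  class_names = fit$class_names)
  } else {
    function(img) cluster_rcnn_detect(fit$model, img, score_thresh = fit$config$conf_thresh,
                                      class_names = fit$class_names,
                                      proposal_budget = c(300L, 50L))
  }
  dets <- purrr::map_dfr(seq_len(nrow(fit$val)), function(i) {
    d <- detect_fn(fit$val$image[[i]])
    if (nrow(d)) d$image_id <- fit$val$image_id[i]
    d
  })
  if (!nrow(dets)) {
    dets <- empty_detections()
    dets$image_id <- character(0)
  }
  evaluate_detections(dets, fit$val, iou_thresh)
}
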