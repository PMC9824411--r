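#' Specify a multi-branch Inception block
#'
#' The block runs several convolution kernels of different sizes in parallel
#' on the same input and concatenates the branch outputs along channels.
#' Variant A uses four branches with kernels 1, 3, 5, 7 split 1:1:1:1;
#' variant B uses three branches with kernels 1, 3, 7 split 2:1:1. In both
#' variants the kernel-1 branch is a 3x3 stride-1 max-pool followed by a 1x1
#' convolution (the pooling path folded into that branch's channel budget),
#' and the 7x7 branch is preceded by a 1x1 bottleneck (default 128 channels,
#' capped at half the input width) that cuts its parameter count by roughly
#' three quarters. The block is channel-preserving: the branch output
#' channels sum to `in_channels`, so it drops into a host network without
#' disturbing any tensor shape.
#'
#' @param variant `"A"` or `"B"`.
#' @param in_channels input (= output) channel count; must be divisible by
#'   the ratio total.
#' @param branch_kernels odd kernel sizes per branch (defaults by variant).
#' @param branch_ratio output-channel proportions per branch (defaults by
#'   variant).
#' @param bottleneck_channels 1x1 width before the 7x7 kernel.
#' @return An `inception_spec` list.
#' @export
inception_spec <- function(variant = c("A", "B"), in_channels,
                           branch_kernels = NULL, branch_ratio = NULL,
                           bottleneck_channels = NULL) {
  variant <- match.arg(variant)
  if (is.null(branch_kernels)) {
    branch_kernels <- if (variant == "A") c(1, 3, 5, 7) else c(1, 3, 7)
  }
  if (is.null(branch_ratio)) {
    branch_ratio <- if (variant == "A") c(1, 1, 1, 1) else c(2, 1, 1)
  }
  if (length(branch_kernels) != length(branch_ratio)) {
    abort("branch_kernels and branch_ratio must have the same length")
  }
  if (any(branch_kernels %% 2 == 0)) abort("branch kernels must be odd")
  if (in_channels %% sum(branch_ratio) != 0) {
    abort(paste0("channel ratio ", paste(branch_ratio, collapse = ":"),
                 " does not divide in_channels = ", in_channels))
  }
  if (is.null(bottleneck_channels)) {
    bottleneck_channels <- min(128L, in_channels %/% 2L)
  }
  structure(list(variant = variant, in_channels = as.integer(in_channels),
                 branch_kernels = as.integer(branch_kernels),
                 branch_ratio = as.integer(branch_ratio),
                 bottleneck_channels = as.integer(bottleneck_channels)),
            class = "inception_spec")
}

# Graph fragment for one inception block; returns node list and output id.
inception_nodes <- function(prefix, input_id, spec) {
  unit <- spec$in_channels %/% sum(spec$branch_ratio)
  nodes <- list()
  branch_outs <- character()
  for (i in seq_along(spec$branch_kernels)) {
    k <- spec$branch_kernels[i]
    cout <- unit * spec$branch_ratio[i]
    bid <- paste0(prefix, "_b", i)
    if (k == 1) {
      nodes <- c(nodes, list(
        nn_node(paste0(bid, "_pool"), "maxpool", input_id, k = 3L, stride = 1L, pad = 1L),
        nn_node(bid, "conv", paste0(bid, "_pool"), k = 1L,
                cin = spec$in_channels, cout = cout, act = "leaky")
      ))
    } else if (k == 7) {
      nodes <- c(nodes, list(
        nn_node(paste0(bid, "_red"), "conv", input_id, k = 1L,
                cin = spec$in_channels, cout = spec$bottleneck_channels, act = "leaky"),
        nn_node(bid, "conv", paste0(bid, "_red"), k = 7L,
                cin = spec$bottleneck_channels, cout = cout, act = "leaky")
      ))
    } else {
      nodes <- c(nodes, list(
        nn_node(bid, "conv", input_id, k = k,
                cin = spec$in_channels, cout = cout, act = "leaky")
      ))
    }
    branch_outs <- c(branch_outs, bid)
  }
  out_id <- paste0(prefix, "_out")
  nodes <- c(nodes, list(nn_node(out_id, "concat", branch_outs)))
  list(nodes = nodes, out = out_id)
}

#' Build a standalone Inception block
#'
#' Materializes an [inception_spec()] as a runnable network component whose
#' forward contract is `H x W x in_channels -> H x W x in_channels` for any
#' spatial size.
#'
#' @param spec an `inception_spec`.
#' @param seed initialization seed.
#' @return A `pv_inception` object with `$network`, `$params`, `$spec`;
#'   run it with [inception_forward()].
#' @export
build_inception <- function(spec, seed = 1L) {
  frag <- inception_nodes("inc", "in", spec)
  net <- nn_network(c(list(nn_node("in", "input")), frag$nodes), frag$out)
  structure(list(network = net, params = nn_init_params(net, seed), spec = spec),
            class = "pv_inception")
}

#' @rdname build_inception
#' @param module a `pv_inception`.
#' @param x an `H x W x in_channels` array.
#' @export
inception_forward <- function(module, x) {
  nn_forward(module$network, module$params, x, keep_cache = FALSE)$outs[[module$network$outputs]]
}

#' Convolution parameter arithmetic
#'
#' `conv_params()` is the kernel weight count `k^2 * c_in * c_out` (bias
#' excluded). `bottleneck_savings()` is the fraction of those weights removed
#' by replacing a direct `k x k` convolution from `c_in` to `c_out` with a
#' 1x1 reduction to `c_mid` followed by the `k x k` convolution:
#' `1 - (c_in * c_mid + k^2 * c_mid * c_out) / (k^2 * c_in * c_out)`.
#' With a 128-channel bottleneck before a 7x7 kernel at 512 channels the
#' saving is 74.5% — the "about three quarters" rule of thumb.
#'
#' @param k kernel size; `c_in`, `c_out`, `c_mid` channel counts.
#' @return A count (`conv_params`) or a fraction possibly below 0
#'   (`bottleneck_savings`; negative when the bottleneck is wider than it is
#'   worth).
#' @examples
#' conv_params(7, 512, 512)           # 12845056
#' bottleneck_savings(512, 128, 7, 512) # 0.7449
#' @export
conv_params <- function(k, c_in, c_out) {
  stopifnot(k > 0, c_in > 0, c_out > 0)
  k^2 * c_in * c_out
}

#' @rdname conv_params
#' @export
bottleneck_savings <- function(c_in, c_mid, k, c_out) {
  1 - (c_in * c_mid + k^2 * c_mid * c_out) / (k^2 * c_in * c_out)
}
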