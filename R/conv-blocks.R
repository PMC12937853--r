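# Convolutional building blocks:
#  * SHFDEB  - densely connected separable-convolution detail extractor used
#              at the shallowest encoder stage to retain high-frequency
#              spatial detail.
#  * MDCB-P  - parallel multi-scale depth-wise convolution block (one
#              depth-wise branch per kernel size, summed, pointwise mixed,
#              residual).
#  * MDCB-S  - serial large-kernel depth-wise bottleneck (pointwise
#              expansion, sequential depth-wise convolutions, pointwise
#              projection, residual).

#' Configure a shallow high-frequency dense extraction block
#'
#' A stack of `n_layers` separable convolutions (3x3 depth-wise followed by
#' a 1x1 pointwise map to `growth_channels`) with dense connectivity: layer
#' i receives the channel concatenation of the block input and all previous
#' layer outputs. A final 1x1 projection fixes the output channel count.
#'
#' @param in_channels input channels.
#' @param growth_channels channels added by each dense layer.
#' @param n_layers number of dense layers (>= 2).
#' @param out_channels channels of the projected block output.
#' @param norm,act batch normalization / activation of each unit (exposed
#'   for frozen-kernel verification).
#' @return an `shfdeb_config` module.
#' @export
shfdeb_config <- function(in_channels, growth_channels = 16L, n_layers = 4L,
                          out_channels = 32L, norm = TRUE,
                          act = c("relu", "none")) {
  act <- match.arg(act)
  if (n_layers < 2L) stop("n_layers must be >= 2 (dense connectivity)")
  layers <- vector("list", n_layers)
  cin <- in_channels
  for (i in seq_len(n_layers)) {
    layers[[i]] <- list(
      dw = nn_depthwise(cin, 3L, norm = FALSE, act = "none"),
      pw = nn_conv(cin, growth_channels, 1L, norm = norm, act = act)
    )
    cin <- cin + growth_channels
  }
  m <- list(type = "shfdeb", in_channels = in_channels,
            growth_channels = growth_channels, n_layers = n_layers,
            out_channels = out_channels, layers = layers,
            proj = nn_conv(cin, out_channels, 1L, norm = norm, act = act))
  class(m) <- c("shfdeb_config", "nn_module")
  m
}

shfdeb_forward_ag <- function(cfg, x, train = FALSE) {
  feats <- list(x)
  for (layer in cfg$layers) {
    inp <- if (length(feats) == 1L) feats[[1]] else ag_concat_c(feats)
    y <- module_forward(layer$pw, ag_depthwise(inp, layer$dw$w, layer$dw$b), train)
    feats[[length(feats) + 1L]] <- y
  }
  module_forward(cfg$proj, ag_concat_c(feats), train)
}

#' Apply an SHFDEB block to a feature map
#'
#' @param x feature map `(H, W, C)` with `C == cfg$in_channels`.
#' @param cfg an [shfdeb_config()] module.
#' @param train use batch statistics in normalization layers.
#' @return feature map `(H, W, cfg$out_channels)`; spatial shape preserved.
#' @export
shfdeb_forward <- function(x, cfg, train = FALSE) {
  x4 <- to4(as.array(x))
  if (dim(x4)[3] != cfg$in_channels) {
    stop("shape error: input has ", dim(x4)[3], " channels, config expects ",
         cfg$in_channels)
  }
  out <- ag_no_grad(shfdeb_forward_ag(cfg, ag_const(x4), train))
  from4(out$value, 3L)
}

#' Configure a multi-scale depth-wise convolution block
#'
#' Shared configuration for the parallel ([mdcb_parallel_forward()]) and
#' serial ([mdcb_serial_forward()]) variants. All kernel sizes must be odd
#' so symmetric padding preserves shape.
#'
#' @param channels feature channels (preserved by both blocks).
#' @param kernel_sizes odd kernel sizes: parallel branches for MDCB-P
#'   (default 3, 5, 7), sequential stages for MDCB-S (default 7, 9).
#' @param expansion bottleneck width multiplier of MDCB-S (default 2).
#' @param variant `"parallel"` or `"serial"`.
#' @param norm,act normalization / activation toggles (identity-kernel tests
#'   disable them).
#' @return an `mdcb_config` module.
#' @export
mdcb_config <- function(channels,
                        kernel_sizes = NULL,
                        expansion = 2,
                        variant = c("parallel", "serial"),
                        norm = TRUE, act = c("relu", "none")) {
  variant <- match.arg(variant)
  act <- match.arg(act)
  if (is.null(kernel_sizes)) {
    kernel_sizes <- if (variant == "parallel") c(3L, 5L, 7L) else c(7L, 9L)
  }
  if (any(kernel_sizes %% 2L == 0L)) {
    stop("configuration error: all kernel sizes must be odd")
  }
  m <- list(type = paste0("mdcb_", variant), channels = channels,
            kernel_sizes = as.integer(kernel_sizes), expansion = expansion,
            norm = norm, act = act)
  if (variant == "parallel") {
    m$branches <- lapply(m$kernel_sizes, function(k) {
      nn_depthwise(channels, k, norm = FALSE, act = "none")
    })
    m$mix <- nn_conv(channels, channels, 1L, norm = norm, act = act)
  } else {
    ce <- max(1L, as.integer(round(channels * expansion)))
    m$expanded_channels <- ce
    m$expand <- nn_conv(channels, ce, 1L, norm = norm, act = act)
    m$dws <- lapply(m$kernel_sizes, function(k) {
      nn_depthwise(ce, k, norm = norm, act = act)
    })
    m$project <- nn_conv(ce, channels, 1L, norm = norm, act = act)
  }
  class(m) <- c("mdcb_config", "nn_module")
  m
}

mdcb_parallel_ag <- function(cfg, x, train = FALSE) {
  acc <- NULL
  for (br in cfg$branches) {
    y <- ag_depthwise(x, br$w, br$b)
    acc <- if (is.null(acc)) y else ag_add(acc, y)
  }
  ag_add(module_forward(cfg$mix, acc, train), x)
}

mdcb_serial_ag <- function(cfg, x, train = FALSE) {
  y <- module_forward(cfg$expand, x, train)
  for (dw in cfg$dws) y <- module_forward(dw, y, train)
  ag_add(module_forward(cfg$project, y, train), x)
}

check_mdcb_input <- function(x4, cfg) {
  if (dim(x4)[3] != cfg$channels) {
    stop("shape error: input has ", dim(x4)[3], " channels, config expects ",
         cfg$channels)
  }
}

#' Parallel multi-scale depth-wise block (MDCB-P)
#'
#' One depth-wise branch per configured kernel size, branch outputs summed,
#' mixed by a pointwise convolution, with a residual connection from the
#' input. Shape is preserved.
#'
#' @param x feature map `(H, W, C)` with `C == cfg$channels`.
#' @param cfg an [mdcb_config()] with `variant = "parallel"`.
#' @param train use batch statistics in normalization layers.
#' @return feature map with the input's shape.
#' @export
mdcb_parallel_forward <- function(x, cfg, train = FALSE) {
  x4 <- to4(as.array(x))
  check_mdcb_input(x4, cfg)
  out <- ag_no_grad(mdcb_parallel_ag(cfg, ag_const(x4), train))
  from4(out$value, 3L)
}

#' Serial large-kernel depth-wise bottleneck (MDCB-S)
#'
#' Pointwise expansion by `cfg$expansion`, the configured depth-wise
#' convolutions applied in sequence, pointwise projection back to the input
#' width, and a residual connection. The depth-wise chain has theoretical
#' receptive field `1 + sum(k_i - 1)`.
#'
#' @inheritParams mdcb_parallel_forward
#' @param cfg an [mdcb_config()] with `variant = "serial"`.
#' @return feature map with the input's shape.
#' @export
mdcb_serial_forward <- function(x, cfg, train = FALSE) {
  x4 <- to4(as.array(x))
  check_mdcb_input(x4, cfg)
  out <- ag_no_grad(mdcb_serial_ag(cfg, ag_const(x4), train))
  from4(out$value, 3L)
}
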