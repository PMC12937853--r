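# Wavelet Split and Fusion Block (WSFB): single-level orthonormal Haar
# analysis/synthesis, soft-threshold denoising of the detail bands, a
# learnable high-frequency pathway, low-frequency fusion with encoder
# features, and the final high/low-frequency fusion.
#
# Band-to-axis convention (fixed and tested): for each 2x2 block
#   a b      ll = (a+b+c+d)/2    lh = (a+b-c-d)/2   (variation across rows)
#   c d      hl = (a-b+c-d)/2    hh = (a-b-c+d)/2
# The analysis is orthonormal, so energy is preserved and the synthesis is
# the exact transpose/inverse.

# internal: x is (H, W, C, N) with even spatial dims -> (H/2, W/2, 4C, N)
# stacked band-major: [ll | lh | hl | hh], C channels each.
haar_core_dec <- function(x) {
  d <- dim(x)
  io <- seq(1L, d[1], by = 2L); ie <- seq(2L, d[1], by = 2L)
  jo <- seq(1L, d[2], by = 2L); je <- seq(2L, d[2], by = 2L)
  a <- x[io, jo, , , drop = FALSE]; b <- x[io, je, , , drop = FALSE]
  cc <- x[ie, jo, , , drop = FALSE]; dd <- x[ie, je, , , drop = FALSE]
  out <- array(0, dim = c(d[1] / 2, d[2] / 2, 4 * d[3], d[4]))
  C <- d[3]
  out[, , seq_len(C), ] <- (a + b + cc + dd) / 2
  out[, , C + seq_len(C), ] <- (a + b - cc - dd) / 2
  out[, , 2 * C + seq_len(C), ] <- (a - b + cc - dd) / 2
  out[, , 3 * C + seq_len(C), ] <- (a - b - cc + dd) / 2
  out
}

haar_core_rec <- function(bands) {
  d <- dim(bands)
  C <- d[3] / 4
  ll <- bands[, , seq_len(C), , drop = FALSE]
  lh <- bands[, , C + seq_len(C), , drop = FALSE]
  hl <- bands[, , 2 * C + seq_len(C), , drop = FALSE]
  hh <- bands[, , 3 * C + seq_len(C), , drop = FALSE]
  x <- array(0, dim = c(2 * d[1], 2 * d[2], C, d[4]))
  io <- seq(1L, 2 * d[1], by = 2L); ie <- seq(2L, 2 * d[1], by = 2L)
  jo <- seq(1L, 2 * d[2], by = 2L); je <- seq(2L, 2 * d[2], by = 2L)
  x[io, jo, , ] <- (ll + lh + hl + hh) / 2
  x[io, je, , ] <- (ll + lh - hl - hh) / 2
  x[ie, jo, , ] <- (ll - lh + hl - hh) / 2
  x[ie, je, , ] <- (ll - lh - hl + hh) / 2
  x
}

# autograd wrappers: the transform is orthonormal, so each backward pass is
# the opposite transform applied to the gradient.
ag_haar_dec <- function(x) {
  x <- as_node(x)
  ag_node(haar_core_dec(x$value), list(x), function(self) {
    ag_accum(x, haar_core_rec(self$grad))
  })
}

ag_haar_rec <- function(bands) {
  bands <- as_node(bands)
  ag_node(haar_core_rec(bands$value), list(bands), function(self) {
    ag_accum(bands, haar_core_dec(self$grad))
  })
}

# ---- array-rank plumbing ----------------------------------------------------

# Feature maps are matrices (H, W), arrays (H, W, C), or batches (H, W, C, N).
to4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature map must be a matrix or array")
  if (length(d) == 2L) x <- array(x, dim = c(d, 1L, 1L))
  else if (length(d) == 3L) x <- array(x, dim = c(d, 1L))
  else if (length(d) != 4L) stop("feature map must have 2, 3 or 4 dimensions")
  x
}

from4 <- function(x, rank) {
  d <- dim(x)
  if (rank == 2L) array(x, dim = d[1:2]) else if (rank == 3L) array(x, dim = d[1:3]) else x
}

rank_of <- function(x) length(dim(x))

#' Single-level 2-D Haar decomposition
#'
#' Applies the orthonormal single-level Haar wavelet transform per channel,
#' splitting a feature map into a half-resolution approximation band `ll`
#' and three detail bands: `lh` (variation across rows, i.e. horizontal
#' edges), `hl` (variation across columns), and `hh` (diagonal). The
#' transform is orthonormal: the summed squared energy of the four bands
#' equals that of the input, and [haar_reconstruct()] inverts it exactly.
#' Odd spatial dimensions are reflect-padded by one pixel on the trailing
#' edge before analysis; [haar_reconstruct()] crops back.
#'
#' @param x feature map: matrix `(H, W)` or array `(H, W, C)` / `(H, W, C, N)`.
#' @return object of class `wavelet_bands`: list with `ll`, `lh`, `hl`, `hh`,
#'   each at half the (padded) input resolution and the input's rank.
#' @examples
#' b <- haar_decompose(matrix(c(1, 3, 2, 4), 2, 2))
#' c(b$ll, b$lh, b$hl, b$hh)  # 5 -2 -1 0
#' @export
haar_decompose <- function(x) {
  rk <- rank_of(if (is.null(dim(x))) as.matrix(x) else x)
  x4 <- to4(x)
  d <- dim(x4)
  orig <- d[1:2]
  if (d[1] %% 2L == 1L) x4 <- x4[c(seq_len(d[1]), d[1]), , , , drop = FALSE]
  if (d[2] %% 2L == 1L) x4 <- x4[, c(seq_len(d[2]), d[2]), , , drop = FALSE]
  stacked <- haar_core_dec(x4)
  C <- d[3]
  bands <- list(
    ll = from4(stacked[, , seq_len(C), , drop = FALSE], rk),
    lh = from4(stacked[, , C + seq_len(C), , drop = FALSE], rk),
    hl = from4(stacked[, , 2 * C + seq_len(C), , drop = FALSE], rk),
    hh = from4(stacked[, , 3 * C + seq_len(C), , drop = FALSE], rk)
  )
  attr(bands, "orig_spatial") <- orig
  attr(bands, "rank") <- rk
  class(bands) <- "wavelet_bands"
  bands
}

#' Inverse single-level Haar transform
#'
#' Exact inverse of [haar_decompose()] on its image (orthonormal synthesis).
#'
#' @param bands a `wavelet_bands` object, or a plain list with elements
#'   `ll`, `lh`, `hl`, `hh` of identical shape.
#' @return the reconstructed feature map.
#' @export
haar_reconstruct <- function(bands) {
  dims <- lapply(bands[c("ll", "lh", "hl", "hh")], dim_of)
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stop("shape mismatch among wavelet bands")
  }
  b4 <- lapply(bands[c("ll", "lh", "hl", "hh")], function(b) to4(as.array(b)))
  stacked <- array(0, dim = c(dim(b4$ll)[1:2], 4 * dim(b4$ll)[3], dim(b4$ll)[4]))
  C <- dim(b4$ll)[3]
  stacked[, , seq_len(C), ] <- b4$ll
  stacked[, , C + seq_len(C), ] <- b4$lh
  stacked[, , 2 * C + seq_len(C), ] <- b4$hl
  stacked[, , 3 * C + seq_len(C), ] <- b4$hh
  x <- haar_core_rec(stacked)
  orig <- attr(bands, "orig_spatial")
  if (!is.null(orig)) x <- x[seq_len(orig[1]), seq_len(orig[2]), , , drop = FALSE]
  rk_out <- attr(bands, "rank")
  if (is.null(rk_out)) rk_out <- max(2L, rank_of(as.array(bands$ll)))
  from4(x, rk_out)
}

#' Soft-threshold shrinkage
#'
#' Elementwise `sign(v) * max(|v| - t, 0)`, the shrinkage operator used to
#' denoise the high-frequency wavelet coefficients.
#'
#' @param band numeric array of coefficients.
#' @param t nonnegative threshold.
#' @return shrunken coefficients, same shape as `band`.
#' @export
soft_threshold <- function(band, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("soft threshold `t` must be a single nonnegative number")
  }
  sign(band) * pmax(abs(band) - t, 0)
}

# ---- WSFB learnable module --------------------------------------------------

#' Configure a Wavelet Split and Fusion Block
#'
#' Creates the learnable parts of a WSFB: the high-frequency pathway (two
#' 3x3 convolution units applied to the soft-thresholded, channel-
#' concatenated detail bands), the low-frequency fusion (1x1 projection of
#' the `ll` band concatenated with an encoder feature), and the final 1x1
#' fusion convolution. `norm`/`act` disable batch normalization and the ReLU
#' for frozen-kernel verification.
#'
#' @param in_channels channels of the feature the wavelet transform is
#'   applied to (each band then has `in_channels` channels).
#' @param enc_channels channels of the encoder feature fused on the
#'   low-frequency path.
#' @param fused_channels output channels of all three pathways.
#' @param soft_threshold shrinkage threshold applied to the detail bands
#'   (default 0.05, on features of roughly unit scale).
#' @param norm,act whether the convolution units carry batch normalization
#'   and a ReLU.
#' @return a `wsfb_config` module.
#' @export
wsfb_config <- function(in_channels, enc_channels = in_channels,
                        fused_channels = in_channels,
                        soft_threshold = 0.05, norm = TRUE,
                        act = c("relu", "none")) {
  act <- match.arg(act)
  if (soft_threshold < 0) stop("soft_threshold must be >= 0")
  m <- list(
    type = "wsfb",
    soft_threshold = soft_threshold,
    in_channels = in_channels,
    fused_channels = fused_channels,
    high1 = nn_conv(3L * in_channels, fused_channels, 3L, norm = norm, act = act),
    high2 = nn_conv(fused_channels, fused_channels, 3L, norm = norm, act = act),
    low = nn_conv(in_channels + enc_channels, fused_channels, 1L,
                  norm = norm, act = act),
    fuse = nn_conv(2L * fused_channels, fused_channels, 1L,
                   norm = norm, act = act)
  )
  class(m) <- c("wsfb_config", "nn_module")
  m
}

# internal ag versions -------------------------------------------------------

wsfb_high_ag <- function(cfg, lh, hl, hh, train = FALSE) {
  detail <- ag_concat_c(list(
    ag_soft_threshold(lh, cfg$soft_threshold),
    ag_soft_threshold(hl, cfg$soft_threshold),
    ag_soft_threshold(hh, cfg$soft_threshold)
  ))
  module_forward(cfg$high2, module_forward(cfg$high1, detail, train), train)
}

wsfb_low_ag <- function(cfg, ll, enc, train = FALSE) {
  de <- dim(enc$value)
  dl <- dim(ll$value)
  if (dl[1] != de[1] || dl[2] != de[2]) {
    ll <- ag_resize_bilinear(ll, de[1], de[2])
  }
  module_forward(cfg$low, ag_concat_c(list(ll, enc)), train)
}

wsfb_fuse_ag <- function(cfg, fh, fl, train = FALSE) {
  dh <- dim(fh$value); dl <- dim(fl$value)
  if (dh[1] < dl[1] || dh[2] < dl[2]) {
    stop("shape error: high-frequency feature is smaller than the low-frequency feature")
  }
  if (dh[1] > dl[1] || dh[2] > dl[2]) {
    if (dh[1] %% dl[1] != 0L || dh[2] %% dl[2] != 0L || dh[1] %/% dl[1] != dh[2] %/% dl[2]) {
      stop("shape error: high/low spatial sizes are not an integer factor apart")
    }
    fh <- ag_avgpool(fh, dh[1] %/% dl[1])
  }
  module_forward(cfg$fuse, ag_concat_c(list(fh, fl)), train)
}

# full block used by the network: x is the higher-resolution feature to be
# wavelet-split; enc is the encoder feature at band resolution.
wsfb_forward_ag <- function(cfg, x, enc, train = FALSE) {
  x <- ag_pad_to_even(x)
  bands <- ag_haar_dec(x)
  C <- dim(x$value)[3]
  ll <- ag_slice_c(bands, seq_len(C))
  lh <- ag_slice_c(bands, C + seq_len(C))
  hl <- ag_slice_c(bands, 2 * C + seq_len(C))
  hh <- ag_slice_c(bands, 3 * C + seq_len(C))
  fh <- wsfb_high_ag(cfg, lh, hl, hh, train)
  fl <- wsfb_low_ag(cfg, ll, enc, train)
  wsfb_fuse_ag(cfg, fh, fl, train)
}

# ---- public functional surface ---------------------------------------------

bands_to_nodes <- function(bands) {
  lapply(bands[c("ll", "lh", "hl", "hh")], function(b) ag_const(to4(as.array(b))))
}

#' High-frequency WSFB pathway
#'
#' Soft-thresholds the `lh`/`hl`/`hh` detail bands, concatenates them on the
#' channel axis, and applies the block's two 3x3 convolution units. Output
#' spatial shape equals the band shape; output channels equal
#' `cfg$fused_channels`.
#'
#' @param bands a `wavelet_bands` object.
#' @param cfg a [wsfb_config()] module.
#' @param train use batch statistics in the normalization layers.
#' @return feature map `(Hb, Wb, fused_channels)`.
#' @export
highfreq_path <- function(bands, cfg, train = FALSE) {
  nb <- bands_to_nodes(bands)
  out <- ag_no_grad(wsfb_high_ag(cfg, nb$lh, nb$hl, nb$hh, train))
  from4(out$value, 3L)
}

#' Low-frequency WSFB pathway
#'
#' Fuses the `ll` approximation band with an encoder feature by channel
#' concatenation and a 1x1 projection. If the spatial shapes differ, `ll`
#' is bilinearly resampled to the encoder feature's shape.
#'
#' @param ll approximation band, matrix or `(H, W, C)` array.
#' @param encoder_feature encoder feature map.
#' @inheritParams highfreq_path
#' @return feature map with the encoder feature's spatial shape and
#'   `cfg$fused_channels` channels.
#' @export
lowfreq_path <- function(ll, encoder_feature, cfg, train = FALSE) {
  out <- ag_no_grad(
    wsfb_low_ag(cfg, ag_const(to4(as.array(ll))),
                ag_const(to4(as.array(encoder_feature))), train))
  from4(out$value, 3L)
}

#' High/low-frequency fusion
#'
#' Average-pools the high-frequency feature down to the low-frequency
#' feature's spatial shape, concatenates on channels, and compresses with
#' the block's 1x1 convolution unit (batch normalization + ReLU), so all
#' outputs are nonnegative.
#'
#' @param fh high-frequency pathway output (spatial dims >= those of `fl`).
#' @param fl low-frequency pathway output.
#' @inheritParams highfreq_path
#' @return fused feature `(dim(fl)[1], dim(fl)[2], fused_channels)`.
#' @export
wsfb_fuse <- function(fh, fl, cfg, train = FALSE) {
  out <- ag_no_grad(
    wsfb_fuse_ag(cfg, ag_const(to4(as.array(fh))),
                 ag_const(to4(as.array(fl))), train))
  from4(out$value, 3L)
}
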