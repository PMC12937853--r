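# Context-Weighted Attention Module (CWAM): decomposes a sigmoid saliency
# map into foreground / background / uncertainty evidence, injects the
# uncertainty map back into the upsampled saliency, and runs single-head
# scaled dot-product attention over the spatial tokens of the fused feature,
# with a residual connection from the decoder feature.

#' Decompose a saliency map at a confidence threshold
#'
#' Splits a saliency map `f_m` (values in `[0, 1]`) into foreground evidence
#' `m_f = max(f_m - t, 0)`, background evidence `m_b = max(t - f_m, 0)`, and
#' an uncertainty map `m_u = t - |f_m - t|`. For `t = 0.5` the three maps sum
#' to 0.5 everywhere, and foreground and background evidence are mutually
#' exclusive (`m_f * m_b = 0`); `m_u` peaks exactly where `f_m = t`.
#'
#' @param f_m numeric array of saliency values in `[0, 1]` (sigmoid
#'   activated; values outside the unit interval raise an error to catch
#'   un-activated logits).
#' @param threshold decision threshold in `(0, 1)` (default 0.5).
#' @return object of class `saliency_decomposition`: list with `m_f`, `m_b`,
#'   `m_u` (same shape as `f_m`) and `threshold`.
#' @export
decompose_saliency <- function(f_m, threshold = 0.5) {
  if (!all(is.finite(f_m))) stop("value error: saliency map contains non-finite values")
  if (min(f_m) < 0 || max(f_m) > 1) {
    stop("value error: saliency values must lie in [0, 1]; got range [",
         signif(min(f_m), 4), ", ", signif(max(f_m), 4),
         "] - apply a sigmoid first")
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  out <- list(m_f = pmax(f_m - threshold, 0),
              m_b = pmax(threshold - f_m, 0),
              m_u = threshold - abs(f_m - threshold),
              threshold = threshold)
  class(out) <- "saliency_decomposition"
  out
}

#' Inject uncertainty evidence into upsampled features
#'
#' Adds the uncertainty map elementwise to the (upsampled) deep feature. A
#' single-channel `m_u` is broadcast across the channels of `f_m_up`.
#'
#' @param f_m_up feature map (matrix or `(H, W, C)` array).
#' @param m_u uncertainty map with the same spatial shape.
#' @return `f_m_up + m_u`, same shape as `f_m_up`.
#' @export
enhance_uncertain <- function(f_m_up, m_u) {
  df <- dim_of(f_m_up)
  du <- dim_of(m_u)
  if (!identical(as.integer(df[1:2]), as.integer(du[1:2]))) {
    stop("shape error: spatial shapes differ (",
         paste(df[1:2], collapse = "x"), " vs ", paste(du[1:2], collapse = "x"), ")")
  }
  if (length(df) > 2L && (length(du) == 2L || du[3] == 1L) && df[3] > 1L) {
    m_u <- array(rep(as.numeric(m_u), df[3]), dim = df)
  } else if (!identical(as.integer(df), as.integer(du))) {
    stop("shape error: incompatible shapes")
  }
  f_m_up + m_u
}

#' Configure a context-weighted attention module
#'
#' Holds the three 1x1 projection layers producing the query, key and value
#' maps from the fused feature, and the token-count cap above which keys and
#' values are average-pooled before attention (a memory contract, never an
#' error).
#'
#' @param channels channels of the decoder feature gated by the module.
#' @param attention_resolution_cap maximum number of spatial tokens in the
#'   key/value maps before average pooling (default 4096).
#' @param threshold saliency decomposition threshold (default 0.5).
#' @return a `cwam_config` module.
#' @export
cwam_config <- function(channels, attention_resolution_cap = 4096L,
                        threshold = 0.5) {
  if (attention_resolution_cap < 1L) stop("attention_resolution_cap must be >= 1")
  m <- list(
    type = "cwam", channels = channels,
    cap = as.integer(attention_resolution_cap),
    threshold = threshold,
    q = nn_conv(channels + 1L, channels, 1L, bias = TRUE, norm = FALSE, act = "none"),
    k = nn_conv(channels + 1L, channels, 1L, bias = TRUE, norm = FALSE, act = "none"),
    v = nn_conv(channels + 1L, channels, 1L, bias = TRUE, norm = FALSE, act = "none")
  )
  class(m) <- c("cwam_config", "nn_module")
  m
}

cwam_forward_ag <- function(cfg, f_m, f_l, train = FALSE) {
  dl <- dim(f_l$value)
  f_m_up <- ag_resize_bilinear(f_m, dl[1], dl[2])
  m_u <- ag_uncertainty(f_m_up, cfg$threshold)
  enhanced <- ag_add(f_m_up, m_u)
  fprime <- ag_concat_c(list(enhanced, f_l))
  q <- module_forward(cfg$q, fprime, train)
  k <- module_forward(cfg$k, fprime, train)
  v <- module_forward(cfg$v, fprime, train)
  while (prod(dim(k$value)[1:2]) > cfg$cap &&
         dim(k$value)[1] %% 2L == 0L && dim(k$value)[2] %% 2L == 0L) {
    k <- ag_avgpool(k, 2L)
    v <- ag_avgpool(v, 2L)
  }
  ag_add(ag_attention(q, k, v), f_l)
}

#' Context-weighted attention over a decoder feature
#'
#' Upsamples the single-channel saliency map `f_m` to the decoder feature's
#' spatial shape, adds its uncertainty map, concatenates the enhanced map
#' with the decoder feature `f_l`, projects to query/key/value with 1x1
#' convolutions, applies single-head scaled dot-product attention over
#' spatial tokens (row-softmax of \eqn{Q^T K / \sqrt{d}}), and adds a
#' residual from `f_l`. If the token count exceeds
#' `cfg$attention_resolution_cap`, keys and values are average-pooled.
#'
#' @param f_m single-channel saliency map (matrix or `(H', W', 1)` array)
#'   with values in `[0, 1]`.
#' @param f_l decoder feature map `(H, W, C)` with `C == cfg$channels`.
#' @param cfg a [cwam_config()] module.
#' @param train use batch statistics in normalization layers.
#' @return feature map with the shape of `f_l`.
#' @export
cwam_forward <- function(f_m, f_l, cfg, train = FALSE) {
  if (!all(is.finite(f_m)) || !all(is.finite(f_l))) {
    stop("value error: non-finite input")
  }
  if (min(f_m) < 0 || max(f_m) > 1) {
    stop("value error: saliency values must lie in [0, 1] - apply a sigmoid first")
  }
  fm4 <- to4(as.array(f_m))
  fl4 <- to4(as.array(f_l))
  if (dim(fm4)[3] != 1L) stop("shape error: f_m must be single channel")
  if (dim(fl4)[3] != cfg$channels) {
    stop("shape error: f_l has ", dim(fl4)[3], " channels, config expects ",
         cfg$channels)
  }
  out <- ag_no_grad(cwam_forward_ag(cfg, ag_const(fm4), ag_const(fl4), train))
  from4(out$value, rank_of(as.array(f_l)))
}
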