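# WMCA-Net assembly: a U-shaped encoder-decoder with a selectable backbone
# (compact residual CNN or windowed-attention transformer), SHFDEB detail
# extraction at the shallowest stage, per-stage WSFB wavelet fusion of
# encoder features concatenated with downsampled detail features, MDCB-S at
# the bottleneck, MDCB-P in the decoder, CWAM gating of each decoder fusion,
# and deep-supervision saliency heads. Every module is a toggle; disabled
# modules become shape-preserving pass-throughs so the whole ablation grid
# is constructible.

#' Network configuration
#'
#' @param backbone `"residual_cnn"` (compact 4-stage residual encoder) or
#'   `"window_transformer"` (patch-merging encoder with windowed single-head
#'   self-attention blocks).
#' @param stage_channels channels of the four encoder stages.
#' @param use_shfdeb,use_wsfb,use_mdcb,use_cwam module toggles; all 16
#'   combinations are valid.
#' @param n_classes 2 (binary notch task) or 5 (knee task).
#' @param deep_supervision attach auxiliary sigmoid saliency heads at the
#'   bottleneck and each decoder stage.
#' @param input_size_px expected square input side, divisible by 16 (four
#'   stages of 2x downsampling).
#' @param attention_resolution_cap token cap for CWAM attention.
#' @return a `network_config` list.
#' @export
network_config <- function(backbone = c("residual_cnn", "window_transformer"),
                           stage_channels = c(16L, 32L, 64L, 128L),
                           use_shfdeb = TRUE, use_wsfb = TRUE,
                           use_mdcb = TRUE, use_cwam = TRUE,
                           n_classes = 2L, deep_supervision = TRUE,
                           input_size_px = 64L,
                           attention_resolution_cap = 4096L) {
  backbone <- match.arg(backbone)
  if (length(stage_channels) != 4L || any(stage_channels < 1)) {
    stop("stage_channels must be 4 positive integers")
  }
  if (input_size_px %% 16L != 0L) {
    stop("input_size_px must be divisible by 16 (four stages of 2x downsampling)")
  }
  if (!n_classes %in% c(2L, 5L)) stop("n_classes must be 2 or 5")
  structure(list(backbone = backbone,
                 stage_channels = as.integer(stage_channels),
                 use_shfdeb = use_shfdeb, use_wsfb = use_wsfb,
                 use_mdcb = use_mdcb, use_cwam = use_cwam,
                 n_classes = as.integer(n_classes),
                 deep_supervision = deep_supervision,
                 input_size_px = as.integer(input_size_px),
                 attention_resolution_cap = as.integer(attention_resolution_cap)),
            class = "network_config")
}

# residual block: two 3x3 conv units with a projection shortcut
nn_resblock <- function(cin, cout, stride = 1L) {
  m <- list(type = "resblock",
            conv1 = nn_conv(cin, cout, 3L, stride = stride),
            conv2 = nn_conv(cout, cout, 3L, act = "none"),
            skip = if (cin != cout || stride != 1L) {
              nn_conv(cin, cout, 1L, stride = stride, act = "none")
            } else NULL)
  class(m) <- c("nn_resblock", "nn_module")
  m
}

#' @exportS3Method
module_forward.nn_resblock <- function(m, x, train = FALSE) {
  y <- module_forward(m$conv2, module_forward(m$conv1, x, train), train)
  s <- if (is.null(m$skip)) x else module_forward(m$skip, x, train)
  ag_relu(ag_add(y, s))
}

# windowed single-head self-attention block (pre-norm) + MLP
nn_swin_block <- function(channels, window = 4L) {
  m <- list(type = "swin", window = as.integer(window),
            ln1 = nn_layernorm(channels),
            q = nn_conv(channels, channels, 1L, bias = TRUE, norm = FALSE, act = "none"),
            k = nn_conv(channels, channels, 1L, bias = TRUE, norm = FALSE, act = "none"),
            v = nn_conv(channels, channels, 1L, bias = TRUE, norm = FALSE, act = "none"),
            proj = nn_conv(channels, channels, 1L, bias = TRUE, norm = FALSE, act = "none"),
            ln2 = nn_layernorm(channels),
            mlp1 = nn_conv(channels, 2L * channels, 1L, bias = TRUE, norm = FALSE, act = "relu"),
            mlp2 = nn_conv(2L * channels, channels, 1L, bias = TRUE, norm = FALSE, act = "none"))
  class(m) <- c("nn_swin_block", "nn_module")
  m
}

#' @exportS3Method
module_forward.nn_swin_block <- function(m, x, train = FALSE) {
  d <- dim(x$value)
  win <- min(m$window, d[1], d[2])
  xa <- ag_space_to_windows(module_forward(m$ln1, x, train), win)
  a <- ag_attention(module_forward(m$q, xa, train),
                    module_forward(m$k, xa, train),
                    module_forward(m$v, xa, train))
  a <- ag_windows_to_space(module_forward(m$proj, a, train), d[1], d[2])
  h <- ag_add(x, a)
  h2 <- module_forward(m$mlp2,
                       module_forward(m$mlp1, module_forward(m$ln2, h, train), train),
                       train)
  ag_add(h, h2)
}

#' Build a WMCA-Net
#'
#' Constructs the full computation graph described by `cfg`. Parameter
#' initialization draws from R's RNG; seed beforehand for reproducible
#' weights.
#'
#' @param cfg a [network_config()].
#' @return a `wmca_net` module list.
#' @export
build_network <- function(cfg) {
  ch <- cfg$stage_channels
  net <- list(type = "wmca_net", config = cfg)

  if (cfg$backbone == "residual_cnn") {
    net$stem <- nn_conv(1L, ch[1], 3L, stride = 2L)
    net$enc1 <- nn_resblock(ch[1], ch[1])
    net$enc2 <- nn_resblock(ch[1], ch[2], stride = 2L)
    net$enc3 <- nn_resblock(ch[2], ch[3], stride = 2L)
    net$enc4 <- nn_resblock(ch[3], ch[4], stride = 2L)
  } else {
    net$stem <- nn_conv(1L, ch[1], 3L, stride = 2L)
    net$enc1 <- nn_swin_block(ch[1])
    net$merge2 <- nn_conv(ch[1], ch[2], 2L, stride = 2L, act = "none")
    net$enc2 <- nn_swin_block(ch[2])
    net$merge3 <- nn_conv(ch[2], ch[3], 2L, stride = 2L, act = "none")
    net$enc3 <- nn_swin_block(ch[3])
    net$merge4 <- nn_conv(ch[3], ch[4], 2L, stride = 2L, act = "none")
    net$enc4 <- nn_swin_block(ch[4])
  }

  if (cfg$use_shfdeb) {
    net$shfdeb <- shfdeb_config(ch[1], growth_channels = 16L, n_layers = 4L,
                                out_channels = ch[1])
    net$skip1_proj <- nn_conv(2L * ch[1], ch[1], 1L)
  }
  if (cfg$use_wsfb) {
    det <- if (cfg$use_shfdeb) ch[1] else 0L
    net$wsfb2 <- wsfb_config(ch[1] + det, enc_channels = ch[2], fused_channels = ch[2])
    net$wsfb3 <- wsfb_config(ch[2] + det, enc_channels = ch[3], fused_channels = ch[3])
    net$wsfb4 <- wsfb_config(ch[3] + det, enc_channels = ch[4], fused_channels = ch[4])
  }
  if (cfg$use_mdcb) {
    net$mdcb_s <- mdcb_config(ch[4], variant = "serial")
    net$mdcb_p3 <- mdcb_config(ch[3], variant = "parallel")
    net$mdcb_p2 <- mdcb_config(ch[2], variant = "parallel")
    net$mdcb_p1 <- mdcb_config(ch[1], variant = "parallel")
  }
  if (cfg$use_cwam) {
    net$cwam3 <- cwam_config(ch[3], cfg$attention_resolution_cap)
    net$cwam2 <- cwam_config(ch[2], cfg$attention_resolution_cap)
    net$cwam1 <- cwam_config(ch[1], cfg$attention_resolution_cap)
  }
  if (cfg$deep_supervision || cfg$use_cwam) {
    net$aux4 <- nn_conv(ch[4], 1L, 1L, bias = TRUE, norm = FALSE, act = "none")
    net$aux3 <- nn_conv(ch[3], 1L, 1L, bias = TRUE, norm = FALSE, act = "none")
    net$aux2 <- nn_conv(ch[2], 1L, 1L, bias = TRUE, norm = FALSE, act = "none")
    net$aux1 <- nn_conv(ch[1], 1L, 1L, bias = TRUE, norm = FALSE, act = "none")
  }

  net$up3 <- nn_conv(ch[4], ch[3], 1L)
  net$dec3 <- nn_conv(2L * ch[3], ch[3], 3L)
  net$up2 <- nn_conv(ch[3], ch[2], 1L)
  net$dec2 <- nn_conv(2L * ch[2], ch[2], 3L)
  net$up1 <- nn_conv(ch[2], ch[1], 1L)
  net$dec1 <- nn_conv(2L * ch[1], ch[1], 3L)
  net$head <- nn_conv(ch[1], cfg$n_classes, 1L, bias = TRUE, norm = FALSE,
                      act = "none")
  class(net) <- c("wmca_net", "nn_module")
  net
}

encode_ag <- function(net, x, train) {
  cfg <- net$config
  s <- module_forward(net$stem, x, train)
  if (cfg$backbone == "residual_cnn") {
    e1 <- module_forward(net$enc1, s, train)
    e2 <- module_forward(net$enc2, e1, train)
    e3 <- module_forward(net$enc3, e2, train)
    e4 <- module_forward(net$enc4, e3, train)
  } else {
    e1 <- module_forward(net$enc1, s, train)
    e2 <- module_forward(net$enc2, module_forward(net$merge2, e1, train), train)
    e3 <- module_forward(net$enc3, module_forward(net$merge3, e2, train), train)
    e4 <- module_forward(net$enc4, module_forward(net$merge4, e3, train), train)
  }
  list(e1, e2, e3, e4)
}

wmca_forward_ag <- function(net, x, train = FALSE) {
  cfg <- net$config
  enc <- encode_ag(net, x, train)
  e1 <- enc[[1]]; e2 <- enc[[2]]; e3 <- enc[[3]]; e4 <- enc[[4]]

  detail <- if (cfg$use_shfdeb) shfdeb_forward_ag(net$shfdeb, e1, train) else NULL

  with_detail <- function(e, factor) {
    if (is.null(detail)) return(e)
    d <- if (factor > 1L) ag_avgpool(detail, factor) else detail
    ag_concat_c(list(e, d))
  }
  skip1 <- if (cfg$use_shfdeb) {
    module_forward(net$skip1_proj, ag_concat_c(list(e1, detail)), train)
  } else e1
  skip2 <- if (cfg$use_wsfb) {
    wsfb_forward_ag(net$wsfb2, with_detail(e1, 1L), e2, train)
  } else e2
  skip3 <- if (cfg$use_wsfb) {
    wsfb_forward_ag(net$wsfb3, with_detail(e2, 2L), e3, train)
  } else e3
  skip4 <- if (cfg$use_wsfb) {
    wsfb_forward_ag(net$wsfb4, with_detail(e3, 4L), e4, train)
  } else e4

  bottom <- if (cfg$use_mdcb) mdcb_serial_ag(net$mdcb_s, skip4, train) else skip4

  has_aux <- cfg$deep_supervision || cfg$use_cwam
  aux <- list()
  aux_head <- function(id, feat) {
    if (!has_aux) return(NULL)
    ag_sigmoid(module_forward(net[[id]], feat, train))
  }
  a4 <- aux_head("aux4", bottom)

  dec_stage <- function(deeper, skip, sal, up_id, dec_id, cwam_id, mdcb_id) {
    ds <- dim(skip$value)
    up <- module_forward(net[[up_id]], ag_resize_bilinear(deeper, ds[1], ds[2]),
                         train)
    g <- if (cfg$use_cwam) cwam_forward_ag(net[[cwam_id]], sal, skip, train) else skip
    y <- module_forward(net[[dec_id]], ag_concat_c(list(up, g)), train)
    if (cfg$use_mdcb) mdcb_parallel_ag(net[[mdcb_id]], y, train) else y
  }
  d3 <- dec_stage(bottom, skip3, a4, "up3", "dec3", "cwam3", "mdcb_p3")
  a3 <- aux_head("aux3", d3)
  d2 <- dec_stage(d3, skip2, a3, "up2", "dec2", "cwam2", "mdcb_p2")
  a2 <- aux_head("aux2", d2)
  d1 <- dec_stage(d2, skip1, a2, "up1", "dec1", "cwam1", "mdcb_p1")
  a1 <- aux_head("aux1", d1)

  dx <- dim(x$value)
  logits <- module_forward(net$head, ag_resize_bilinear(d1, dx[1], dx[2]), train)
  if (cfg$deep_supervision) aux <- list(a4, a3, a2, a1)
  list(logits = logits, aux = aux)
}

check_input_size <- function(d) {
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L) {
    stop("shape error: input spatial size ", d[1], "x", d[2],
         " must be divisible by 16 (four stages of 2x downsampling)")
  }
}

#' Run a forward pass
#'
#' @param net a [build_network()] result.
#' @param images matrix `(H, W)`, array `(H, W, 1)` or batch
#'   `(H, W, 1, N)`; spatial size divisible by 16.
#' @param train use batch statistics in normalization layers (training
#'   mode); in eval mode the forward pass is deterministic given fixed
#'   parameters.
#' @return list with `logits` (`(H, W, n_classes, N)` array) and `aux`
#'   (per-stage sigmoid saliency maps, deepest first, when
#'   `deep_supervision` is set).
#' @export
wmca_forward <- function(net, images, train = FALSE) {
  x <- to4(as.array(images))
  check_input_size(dim(x))
  out <- ag_no_grad(wmca_forward_ag(net, ag_const(x), train))
  list(logits = out$logits$value,
       aux = lapply(out$aux, function(a) if (is.null(a)) NULL else a$value))
}

#' Ablation grid
#'
#' The six incremental module configurations of one backbone family, in
#' ablation-table order: baseline; +SHFDEB; +WSFB; +SHFDEB+WSFB;
#' +SHFDEB+WSFB+MDCB; all modules.
#'
#' @param cfg base [network_config()] whose backbone and shape fields are
#'   kept.
#' @return list of six `network_config`s.
#' @export
ablation_grid <- function(cfg = network_config()) {
  rows <- list(c(FALSE, FALSE, FALSE, FALSE),
               c(TRUE, FALSE, FALSE, FALSE),
               c(FALSE, TRUE, FALSE, FALSE),
               c(TRUE, TRUE, FALSE, FALSE),
               c(TRUE, TRUE, TRUE, FALSE),
               c(TRUE, TRUE, TRUE, TRUE))
  lapply(rows, function(r) {
    out <- cfg
    out$use_shfdeb <- r[1]; out$use_wsfb <- r[2]
    out$use_mdcb <- r[3]; out$use_cwam <- r[4]
    out
  })
}

#' Save / load a network checkpoint
#'
#' The checkpoint carries the full `network_config` (round-tripping
#' bit-exactly), all parameter arrays, and the batch-normalization running
#' statistics.
#'
#' @param net a `wmca_net`.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a rebuilt `wmca_net`.
#' @export
save_checkpoint <- function(net, path) {
  bn <- lapply(collect_bn_states(net), function(e) {
    list(running_mean = e$running_mean, running_var = e$running_var)
  })
  saveRDS(list(config = net$config, params = param_values(net), bn = bn), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- build_network(ck$config)
  set_param_values(net, ck$params)
  states <- collect_bn_states(net)
  for (nm in names(ck$bn)) {
    states[[nm]]$running_mean <- ck$bn[[nm]]$running_mean
    states[[nm]]$running_var <- ck$bn[[nm]]$running_var
  }
  net
}
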