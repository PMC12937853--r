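# Building-block layers on top of the autograd engine. A "module" is a plain
# list with a class tag; trainable leaves are `ag_param` nodes found anywhere
# inside it. `module_forward()` dispatches on the class tag; `train` toggles
# batch-statistics vs running-statistics normalization.

he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

new_bn_state <- function(channels) {
  e <- new.env(parent = emptyenv())
  e$running_mean <- numeric(channels)
  e$running_var <- rep(1, channels)
  e
}

# Convolution unit: conv -> optional batch norm -> optional ReLU.
nn_conv <- function(cin, cout, k = 3L, stride = 1L, bias = TRUE,
                    norm = TRUE, act = c("relu", "none")) {
  act <- match.arg(act)
  m <- list(
    type = "conv",
    k = as.integer(k), stride = as.integer(stride),
    w = ag_param(he_init(k, cin, cout)),
    b = if (bias && !norm) ag_param(numeric(cout)) else NULL,
    norm = norm, act = act
  )
  if (norm) {
    m$gamma <- ag_param(rep(1, cout))
    m$beta <- ag_param(numeric(cout))
    m$bn <- new_bn_state(cout)
  }
  class(m) <- c("nn_conv", "nn_module")
  m
}

# Depth-wise unit (stride 1) with optional norm / activation.
nn_depthwise <- function(channels, k = 3L, bias = FALSE,
                         norm = TRUE, act = c("relu", "none")) {
  act <- match.arg(act)
  m <- list(
    type = "depthwise", k = as.integer(k),
    w = ag_param(array(stats::rnorm(k * k * channels, sd = sqrt(2 / (k * k))),
                       dim = c(k, k, channels))),
    b = if (bias && !norm) ag_param(numeric(channels)) else NULL,
    norm = norm, act = act
  )
  if (norm) {
    m$gamma <- ag_param(rep(1, channels))
    m$beta <- ag_param(numeric(channels))
    m$bn <- new_bn_state(channels)
  }
  class(m) <- c("nn_depthwise", "nn_module")
  m
}

nn_layernorm <- function(channels) {
  m <- list(type = "layernorm",
            gamma = ag_param(rep(1, channels)),
            beta = ag_param(numeric(channels)))
  class(m) <- c("nn_layernorm", "nn_module")
  m
}

module_forward <- function(m, x, train = FALSE) {
  UseMethod("module_forward")
}

#' @exportS3Method
module_forward.nn_conv <- function(m, x, train = FALSE) {
  y <- ag_conv2d(x, m$w, m$b, stride = m$stride)
  if (m$norm) y <- ag_batchnorm(y, m$gamma, m$beta, m$bn, train)
  if (m$act == "relu") y <- ag_relu(y)
  y
}

#' @exportS3Method
module_forward.nn_depthwise <- function(m, x, train = FALSE) {
  y <- ag_depthwise(x, m$w, m$b)
  if (m$norm) y <- ag_batchnorm(y, m$gamma, m$beta, m$bn, train)
  if (m$act == "relu") y <- ag_relu(y)
  y
}

#' @exportS3Method
module_forward.nn_layernorm <- function(m, x, train = FALSE) {
  ag_layernorm_c(x, m$gamma, m$beta)
}

# ---- parameter plumbing -----------------------------------------------------

# Depth-first collection of every ag_param inside a nested module list,
# named by its path ("stage1.w", ...).
collect_params <- function(m, prefix = "") {
  out <- list()
  if (is_ag_node(m)) {
    if (isTRUE(m$is_param)) out[[prefix]] <- m
    return(out)
  }
  if (is.list(m)) {
    nms <- names(m)
    for (i in seq_along(m)) {
      if (is.null(m[[i]])) next
      tag <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      path <- if (nzchar(prefix)) paste0(prefix, ".", tag) else tag
      out <- c(out, collect_params(m[[i]], path))
    }
  }
  out
}

# Batch-norm running statistics, for checkpointing.
collect_bn_states <- function(m, prefix = "") {
  out <- list()
  if (is.environment(m) && !is_ag_node(m)) {
    if (!is.null(m$running_mean)) out[[prefix]] <- m
    return(out)
  }
  if (is.list(m)) {
    nms <- names(m)
    for (i in seq_along(m)) {
      if (is.null(m[[i]])) next
      tag <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      path <- if (nzchar(prefix)) paste0(prefix, ".", tag) else tag
      out <- c(out, collect_bn_states(m[[i]], path))
    }
  }
  out
}

param_values <- function(m) lapply(collect_params(m), function(p) p$value)

set_param_values <- function(m, values) {
  params <- collect_params(m)
  stopifnot(setequal(names(params), names(values)))
  for (nm in names(params)) params[[nm]]$value <- values[[nm]]
  invisible(m)
}

n_params <- function(m) {
  sum(vapply(collect_params(m), function(p) length(p$value), 0))
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- AdamW ------------------------------------------------------------------

# Decoupled weight decay as in AdamW: the decay term is applied directly to
# the parameter, outside the adaptive moment rescaling.
adamw_state <- function(params) {
  st <- list(t = 0L, m = lapply(params, function(p) p$value * 0),
             v = lapply(params, function(p) p$value * 0))
  st
}

adamw_step <- function(params, state, lr, weight_decay = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    p$value <- p$value - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p$value)
  }
  state
}
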