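# Reverse-mode automatic differentiation on dense (H, W, C, N) arrays.
#
# Every differentiable quantity is an `ag_node`: an environment holding the
# forward value, an accumulated gradient, its parents in the computation
# graph, and a closure that pushes the node's gradient back onto its
# parents. Graphs are built implicitly while the forward pass runs and are
# discarded after `ag_backward()`; trainable parameters (`ag_param`) are
# leaves that persist across iterations.

.ag <- new.env(parent = emptyenv())
.ag$grad_enabled <- TRUE
.ag$next_id <- 0L

ag_new_id <- function() {
  .ag$next_id <- .ag$next_id + 1L
  as.character(.ag$next_id)
}

ag_no_grad <- function(expr) {
  old <- .ag$grad_enabled
  .ag$grad_enabled <- FALSE
  on.exit(.ag$grad_enabled <- old)
  force(expr)
}

ag_node <- function(value, parents = list(), backward = NULL,
                    is_param = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$id <- ag_new_id()
  e$is_param <- is_param
  if (.ag$grad_enabled) {
    e$parents <- parents
    e$backward <- backward
    e$needs <- is_param || any(vapply(parents, function(p) p$needs, TRUE))
  } else {
    e$parents <- list()
    e$backward <- NULL
    e$needs <- FALSE
  }
  class(e) <- "ag_node"
  e
}

is_ag_node <- function(x) inherits(x, "ag_node")

ag_const <- function(value) ag_node(value)

ag_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$id <- ag_new_id()
  e$is_param <- TRUE
  e$parents <- list()
  e$backward <- NULL
  e$needs <- TRUE
  class(e) <- "ag_node"
  e
}

as_node <- function(x) if (is_ag_node(x)) x else ag_const(x)

ag_value <- function(x) if (is_ag_node(x)) x$value else x

ag_accum <- function(node, g) {
  if (!node$needs) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Iterative topological sort (DFS) so deep graphs cannot hit R's recursion
# limit; backward visits nodes in reverse topological order exactly once.
ag_backward <- function(loss, seed = NULL) {
  order <- list()
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    if (top$stage == 1L) {
      if (!is.null(visited[[node$id]])) next
      visited[[node$id]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (p$needs && is.null(visited[[p$id]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      order[[length(order) + 1L]] <- node
    }
  }
  if (is.null(seed)) seed <- array(1, dim = dim_of(loss$value))
  loss$grad <- seed
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (!is.null(node$backward) && !is.null(node$grad)) node$backward(node)
  }
  invisible(loss)
}

dim_of <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# ---- elementwise ops --------------------------------------------------------

ag_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_node(a$value + b$value, list(a, b), function(self) {
    ag_accum(a, self$grad)
    ag_accum(b, self$grad)
  })
}

ag_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_node(a$value - b$value, list(a, b), function(self) {
    ag_accum(a, self$grad)
    ag_accum(b, -self$grad)
  })
}

ag_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b), function(self) {
    ag_accum(a, self$grad * bv)
    ag_accum(b, self$grad * av)
  })
}

ag_scale <- function(a, s) {
  a <- as_node(a)
  ag_node(a$value * s, list(a), function(self) ag_accum(a, self$grad * s))
}

ag_div <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  ag_node(av / bv, list(a, b), function(self) {
    ag_accum(a, self$grad / bv)
    ag_accum(b, -self$grad * av / (bv * bv))
  })
}

ag_pow <- function(a, p) {
  a <- as_node(a)
  av <- a$value
  ag_node(av^p, list(a), function(self) {
    ag_accum(a, self$grad * p * av^(p - 1))
  })
}

ag_log_shift <- function(a, eps) {
  a <- as_node(a)
  av <- a$value
  ag_node(log(av + eps), list(a), function(self) {
    ag_accum(a, self$grad / (av + eps))
  })
}

ag_relu <- function(a) {
  a <- as_node(a)
  mask <- a$value > 0
  ag_node(a$value * mask, list(a), function(self) {
    ag_accum(a, self$grad * mask)
  })
}

ag_sigmoid <- function(a) {
  a <- as_node(a)
  s <- 1 / (1 + exp(-a$value))
  ag_node(s, list(a), function(self) {
    ag_accum(a, self$grad * s * (1 - s))
  })
}

# Soft shrinkage sign(v) * max(|v| - t, 0); subgradient 0 inside the dead zone.
ag_soft_threshold <- function(a, t) {
  a <- as_node(a)
  av <- a$value
  mask <- abs(av) > t
  ag_node(sign(av) * pmax(abs(av) - t, 0), list(a), function(self) {
    ag_accum(a, self$grad * mask)
  })
}

# t - |v - t|: the uncertainty map of a saliency decomposition.
ag_uncertainty <- function(a, t) {
  a <- as_node(a)
  av <- a$value
  s <- sign(av - t)
  ag_node(t - abs(av - t), list(a), function(self) {
    ag_accum(a, -self$grad * s)
  })
}

ag_sum <- function(a) {
  a <- as_node(a)
  d <- dim_of(a$value)
  ag_node(sum(a$value), list(a), function(self) {
    ag_accum(a, array(as.numeric(self$grad), dim = d))
  })
}

ag_mean <- function(a) ag_scale(ag_sum(a), 1 / length(as_node(a)$value))

# Sum across the channel axis: (H,W,C,N) -> (H,W,1,N).
ag_sum_c <- function(a) {
  a <- as_node(a)
  d <- dim(a$value)
  hw <- d[1] * d[2]
  y <- array(0, dim = c(d[1], d[2], 1, d[4]))
  A <- array(a$value, dim = c(hw, d[3], d[4]))
  ones <- rep(1, d[3])
  for (n in seq_len(d[4])) y[, , 1, n] <- A[, , n] %*% ones
  ag_node(y, list(a), function(self) {
    g <- self$grad[, , rep(1L, d[3]), , drop = FALSE]
    ag_accum(a, array(g, dim = d))
  })
}

# per-channel sums of an (H,W,C,N) array, in C
channel_sums <- function(x) {
  d <- dim(x)
  rowSums(matrix(colSums(x, dims = 2), d[3], d[4]))
}

# ---- structural ops ---------------------------------------------------------

# Concatenate along the channel axis (dim 3) of (H,W,C,N) arrays.
ag_concat_c <- function(nodes) {
  nodes <- lapply(nodes, as_node)
  vals <- lapply(nodes, function(n) n$value)
  chans <- vapply(vals, function(v) dim(v)[3], 0)
  d <- dim(vals[[1]])
  out <- array(0, dim = c(d[1], d[2], sum(chans), d[4]))
  at <- 0L
  for (v in vals) {
    out[, , at + seq_len(dim(v)[3]), ] <- v
    at <- at + dim(v)[3]
  }
  offsets <- cumsum(c(0L, chans))
  ag_node(out, nodes, function(self) {
    for (i in seq_along(nodes)) {
      idx <- (offsets[i] + 1L):offsets[i + 1L]
      ag_accum(nodes[[i]], self$grad[, , idx, , drop = FALSE])
    }
  })
}

ag_slice_c <- function(a, idx) {
  a <- as_node(a)
  d <- dim(a$value)
  ag_node(a$value[, , idx, , drop = FALSE], list(a), function(self) {
    g <- array(0, dim = d)
    g[, , idx, ] <- self$grad
    ag_accum(a, g)
  })
}

# Broadcast a single-channel map over nc channels.
ag_broadcast_c <- function(a, nc) {
  a <- as_node(a)
  d <- dim(a$value)
  stopifnot(d[3] == 1L)
  out <- array(a$value, dim = c(d[1], d[2], 1, d[4]))[, , rep(1L, nc), , drop = FALSE]
  ag_node(out, list(a), function(self) {
    g <- apply(self$grad, c(1, 2, 4), sum)
    ag_accum(a, array(g, dim = d))
  })
}

ag_pad_to_even <- function(a) {
  a <- as_node(a)
  d <- dim(a$value)
  ph <- d[1] %% 2L
  pw <- d[2] %% 2L
  if (ph == 0L && pw == 0L) return(a)
  v <- a$value
  if (ph == 1L) v <- v[c(seq_len(d[1]), d[1]), , , , drop = FALSE]
  if (pw == 1L) v <- v[, c(seq_len(d[2]), d[2]), , , drop = FALSE]
  ag_node(v, list(a), function(self) {
    g <- self$grad
    if (ph == 1L) {
      g[d[1], , , ] <- g[d[1], , , , drop = FALSE] + g[d[1] + 1L, , , , drop = FALSE]
      g <- g[seq_len(d[1]), , , , drop = FALSE]
    }
    if (pw == 1L) {
      g[, d[2], , ] <- g[, d[2], , , drop = FALSE] + g[, d[2] + 1L, , , drop = FALSE]
      g <- g[, seq_len(d[2]), , , drop = FALSE]
    }
    ag_accum(a, g)
  })
}

ag_crop <- function(a, H, W) {
  a <- as_node(a)
  d <- dim(a$value)
  if (d[1] == H && d[2] == W) return(a)
  ag_node(a$value[seq_len(H), seq_len(W), , , drop = FALSE], list(a),
          function(self) {
    g <- array(0, dim = d)
    g[seq_len(H), seq_len(W), , ] <- self$grad
    ag_accum(a, g)
  })
}

# ---- convolution / pooling / resampling -------------------------------------

# General 2-D convolution via im2col + GEMM. w: (k, k, Cin, Cout); b: Cout or NULL.
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = NULL) {
  x <- as_node(x); w <- as_node(w)
  d <- dim(x$value)
  k <- dim(w$value)[1]
  cin <- dim(w$value)[3]; cout <- dim(w$value)[4]
  stopifnot(d[3] == cin)
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  Ho <- (d[1] + 2L * pad - k) %/% stride + 1L
  Wo <- (d[2] + 2L * pad - k) %/% stride + 1L
  cols <- im2col_cpp(x$value, d[1], d[2], d[3], d[4], k, stride, pad)
  wmat <- t(matrix(w$value, k * k * cin, cout))   # Cout x (k*k*Cin)
  ymat <- wmat %*% cols
  parents <- list(x, w)
  if (!is.null(b)) {
    b <- as_node(b)
    ymat <- ymat + b$value
    parents <- c(parents, list(b))
  }
  y <- array(0, dim = c(Ho, Wo, cout, d[4]))
  # ymat is Cout x (Ho*Wo*N): transpose-free fill via aperm
  y[] <- aperm(array(ymat, dim = c(cout, Ho, Wo, d[4])), c(2, 3, 1, 4))
  ag_node(y, parents, function(self) {
    dy <- matrix(aperm(self$grad, c(3, 1, 2, 4)), nrow = cout)
    if (w$needs) {
      dW <- dy %*% t(cols)  # Cout x (k*k*Cin)
      ag_accum(w, array(t(dW), dim = dim(w$value)))
    }
    if (!is.null(b) && b$needs) ag_accum(b, rowSums(dy))
    if (x$needs) {
      dcols <- t(wmat) %*% dy
      ag_accum(x, col2im_cpp(dcols, d[1], d[2], d[3], d[4], k, stride, pad))
    }
  })
}

# Depth-wise convolution, stride 1, shape-preserving. w: (k, k, C).
ag_depthwise <- function(x, w, b = NULL) {
  x <- as_node(x); w <- as_node(w)
  d <- dim(x$value)
  k <- dim(w$value)[1]
  y <- dw_conv_fwd(x$value, w$value, d[1], d[2], d[3], d[4], k)
  parents <- list(x, w)
  if (!is.null(b)) {
    b <- as_node(b)
    y <- y + array(rep(b$value, each = d[1] * d[2]), dim = d)
    parents <- c(parents, list(b))
  }
  ag_node(y, parents, function(self) {
    g <- dw_conv_bwd(x$value, w$value, self$grad, d[1], d[2], d[3], d[4], k)
    ag_accum(x, g$dx)
    ag_accum(w, g$dw)
    if (!is.null(b) && b$needs) {
      ag_accum(b, channel_sums(self$grad))
    }
  })
}

# Block-average pooling by an integer factor (both spatial dims divisible).
ag_avgpool <- function(x, factor = 2L) {
  x <- as_node(x)
  d <- dim(x$value)
  stopifnot(d[1] %% factor == 0L, d[2] %% factor == 0L)
  Ho <- d[1] %/% factor; Wo <- d[2] %/% factor
  v <- array(x$value, dim = c(factor, Ho, factor, Wo, d[3], d[4]))
  s1 <- colSums(v, dims = 1)                         # (Ho, factor, Wo, C, N)
  s1 <- aperm(s1, c(2, 1, 3, 4, 5))                  # (factor, Ho, Wo, C, N)
  y <- colSums(s1, dims = 1) / (factor * factor)     # (Ho, Wo, C, N)
  ag_node(array(y, dim = c(Ho, Wo, d[3], d[4])), list(x), function(self) {
    g <- self$grad / (factor * factor)
    g6 <- array(0, dim = c(factor, Ho, factor, Wo, d[3], d[4]))
    gsrc <- array(g, dim = c(1, Ho, 1, Wo, d[3], d[4]))
    for (i in seq_len(factor)) for (j in seq_len(factor)) g6[i, , j, , , ] <- gsrc
    ag_accum(x, array(g6, dim = d))
  })
}

# 1-D linear-interpolation matrix (half-pixel-centres convention, clamped
# edges); bilinear resize factorizes into a row and a column application.
interp_matrix <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  if (n_in == 1L) { M[, 1] <- 1; return(M) }
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  lo <- floor(src)
  frac <- src - lo
  hi <- pmin(lo + 1, n_in - 1)
  for (i in seq_len(n_out)) {
    M[i, lo[i] + 1] <- M[i, lo[i] + 1] + (1 - frac[i])
    M[i, hi[i] + 1] <- M[i, hi[i] + 1] + frac[i]
  }
  M
}

apply_row_op <- function(v, M) {
  d <- dim(v)
  out <- M %*% matrix(v, d[1], prod(d[-1]))
  array(out, dim = c(nrow(M), d[-1]))
}

apply_col_op <- function(v, M) {
  d <- dim(v)
  vp <- aperm(v, c(2, 1, 3, 4))
  out <- M %*% matrix(vp, d[2], prod(d[-2]))
  aperm(array(out, dim = c(nrow(M), d[1], d[3], d[4])), c(2, 1, 3, 4))
}

ag_resize_bilinear <- function(x, Ho, Wo) {
  x <- as_node(x)
  d <- dim(x$value)
  if (d[1] == Ho && d[2] == Wo) return(x)
  Mr <- interp_matrix(d[1], Ho)
  Mc <- interp_matrix(d[2], Wo)
  y <- apply_col_op(apply_row_op(x$value, Mr), Mc)
  ag_node(y, list(x), function(self) {
    ag_accum(x, apply_col_op(apply_row_op(self$grad, t(Mr)), t(Mc)))
  })
}

# ---- normalization ----------------------------------------------------------

# Batch normalization over (H, W, N) per channel. `state` is an environment
# carrying running_mean / running_var for inference.
ag_batchnorm <- function(x, gamma, beta, state, training,
                         momentum = 0.1, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  d <- dim(x$value)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mu <- channel_sums(x$value) / m
    va <- channel_sums(x$value^2) / m - mu^2
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * va * m / max(m - 1, 1)
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  invstd <- 1 / sqrt(va + eps)
  mu_b <- array(rep(mu, each = d[1] * d[2]), dim = d)
  is_b <- array(rep(invstd, each = d[1] * d[2]), dim = d)
  xhat <- (x$value - mu_b) * is_b
  ga_b <- array(rep(gamma$value, each = d[1] * d[2]), dim = d)
  be_b <- array(rep(beta$value, each = d[1] * d[2]), dim = d)
  ag_node(xhat * ga_b + be_b, list(x, gamma, beta), function(self) {
    g <- self$grad
    if (gamma$needs) ag_accum(gamma, channel_sums(g * xhat))
    if (beta$needs) ag_accum(beta, channel_sums(g))
    if (x$needs) {
      gx <- g * ga_b
      if (training) {
        s1 <- array(rep(channel_sums(gx) / m, each = d[1] * d[2]), dim = d)
        s2 <- array(rep(channel_sums(gx * xhat) / m, each = d[1] * d[2]), dim = d)
        ag_accum(x, is_b * (gx - s1 - xhat * s2))
      } else {
        ag_accum(x, is_b * gx)
      }
    }
  })
}

# Layer normalization across channels at each (h, w, n) position.
ag_layernorm_c <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  d <- dim(x$value)
  C <- d[3]
  xp <- aperm(x$value, c(3, 1, 2, 4))          # C x spatial
  xm <- matrix(xp, C)
  mu <- colMeans(xm)
  va <- colMeans(xm^2) - mu^2
  invstd <- 1 / sqrt(va + eps)
  xhat <- (xm - rep(mu, each = C)) * rep(invstd, each = C)
  y <- xhat * gamma$value + beta$value
  yarr <- aperm(array(y, dim = c(C, d[1], d[2], d[4])), c(2, 3, 1, 4))
  ag_node(yarr, list(x, gamma, beta), function(self) {
    g <- matrix(aperm(self$grad, c(3, 1, 2, 4)), C)
    if (gamma$needs) ag_accum(gamma, rowSums(g * xhat))
    if (beta$needs) ag_accum(beta, rowSums(g))
    if (x$needs) {
      gx <- g * gamma$value
      s1 <- rep(colMeans(gx), each = C)
      s2 <- rep(colMeans(gx * xhat), each = C)
      dx <- rep(invstd, each = C) * (gx - s1 - xhat * s2)
      ag_accum(x, aperm(array(dx, dim = c(C, d[1], d[2], d[4])), c(2, 3, 1, 4)))
    }
  })
}

# ---- softmax / attention ----------------------------------------------------

# Softmax across the channel axis (class probabilities).
ag_softmax_c <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  C <- d[3]
  xm <- matrix(aperm(x$value, c(3, 1, 2, 4)), C)
  xm <- xm - rep(apply(xm, 2, max), each = C)
  e <- exp(xm)
  p <- e / rep(colSums(e), each = C)
  parr <- aperm(array(p, dim = c(C, d[1], d[2], d[4])), c(2, 3, 1, 4))
  ag_node(parr, list(x), function(self) {
    g <- matrix(aperm(self$grad, c(3, 1, 2, 4)), C)
    dot <- rep(colSums(g * p), each = C)
    dx <- p * (g - dot)
    ag_accum(x, aperm(array(dx, dim = c(C, d[1], d[2], d[4])), c(2, 3, 1, 4)))
  })
}

# Scaled dot-product attention over spatial tokens, batched over N.
# q: (Hq, Wq, C, N); k, v: (Hk, Wk, C, N). Output: (Hq, Wq, C, N).
# Row-softmax of Q^T K / sqrt(C); output_i = sum_j w_ij V_j.
ag_attention <- function(q, k, v) {
  q <- as_node(q); k <- as_node(k); v <- as_node(v)
  dq <- dim(q$value); dk <- dim(k$value)
  C <- dq[3]; N <- dq[4]
  nq <- dq[1] * dq[2]; nk <- dk[1] * dk[2]
  scale <- 1 / sqrt(C)
  # tokens x C per sample, reshaped once for the whole batch
  Qall <- matrix(aperm(q$value, c(1, 2, 4, 3)), nq * N, C)
  Kall <- matrix(aperm(k$value, c(1, 2, 4, 3)), nk * N, C)
  Vall <- matrix(aperm(v$value, c(1, 2, 4, 3)), nk * N, C)
  As <- vector("list", N)
  Oall <- matrix(0, nq * N, C)
  for (n in seq_len(N)) {
    iq <- (n - 1L) * nq + seq_len(nq)
    ik <- (n - 1L) * nk + seq_len(nk)
    S <- tcrossprod(Qall[iq, , drop = FALSE], Kall[ik, , drop = FALSE]) * scale
    S <- S - S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
    E <- exp(S)
    A <- E / rowSums(E)
    Oall[iq, ] <- A %*% Vall[ik, , drop = FALSE]
    As[[n]] <- A
  }
  out <- aperm(array(Oall, dim = c(dq[1], dq[2], N, C)), c(1, 2, 4, 3))
  ag_node(out, list(q, k, v), function(self) {
    gO <- matrix(aperm(self$grad, c(1, 2, 4, 3)), nq * N, C)
    gQ <- matrix(0, nq * N, C); gK <- gV <- matrix(0, nk * N, C)
    for (n in seq_len(N)) {
      iq <- (n - 1L) * nq + seq_len(nq)
      ik <- (n - 1L) * nk + seq_len(nk)
      dO <- gO[iq, , drop = FALSE]
      A <- As[[n]]
      gV[ik, ] <- crossprod(A, dO)
      dA <- tcrossprod(dO, Vall[ik, , drop = FALSE])
      dS <- A * (dA - rowSums(dA * A))
      gQ[iq, ] <- (dS %*% Kall[ik, , drop = FALSE]) * scale
      gK[ik, ] <- crossprod(dS, Qall[iq, , drop = FALSE]) * scale
    }
    unflat <- function(m, d) aperm(array(m, dim = c(d[1], d[2], N, C)), c(1, 2, 4, 3))
    ag_accum(q, unflat(gQ, dq))
    ag_accum(k, unflat(gK, dk))
    ag_accum(v, unflat(gV, dk))
  })
}

# Rearrange (H, W, C, N) into non-overlapping win x win windows stacked along
# the batch axis: output (win, win, C, N * nwin). Pure index permutation.
ag_space_to_windows <- function(x, win) {
  x <- as_node(x)
  d <- dim(x$value)
  stopifnot(d[1] %% win == 0L, d[2] %% win == 0L)
  nh <- d[1] %/% win; nw <- d[2] %/% win
  v <- array(x$value, dim = c(win, nh, win, nw, d[3], d[4]))
  vp <- aperm(v, c(1, 3, 5, 2, 4, 6))
  y <- array(vp, dim = c(win, win, d[3], nh * nw * d[4]))
  ag_node(y, list(x), function(self) {
    g <- array(self$grad, dim = c(win, win, d[3], nh, nw, d[4]))
    gp <- aperm(g, c(1, 4, 2, 5, 3, 6))
    ag_accum(x, array(gp, dim = d))
  })
}

ag_windows_to_space <- function(x, H, W) {
  x <- as_node(x)
  d <- dim(x$value)  # win, win, C, N*nwin
  win <- d[1]
  nh <- H %/% win; nw <- W %/% win
  N <- d[4] %/% (nh * nw)
  v <- array(x$value, dim = c(win, win, d[3], nh, nw, N))
  vp <- aperm(v, c(1, 4, 2, 5, 3, 6))
  y <- array(vp, dim = c(H, W, d[3], N))
  ag_node(y, list(x), function(self) {
    g <- array(self$grad, dim = c(win, nh, win, nw, d[3], N))
    gp <- aperm(g, c(1, 3, 5, 2, 4, 6))
    ag_accum(x, array(gp, dim = d))
  })
}
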