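# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately use plain double loops so they share no
# code path with the implementation they check.

brute_min_dists <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    min(vapply(seq_len(nrow(b)), function(j) {
      sqrt(sum((a[i, ] - b[j, ])^2))
    }, 0))
  }, 0)
}

brute_hd95 <- function(a, b) {
  d <- c(brute_min_dists(a, b), brute_min_dists(b, a))
  unname(quantile(d, 0.95, type = 7))
}

brute_assd <- function(a, b) {
  (sum(brute_min_dists(a, b)) + sum(brute_min_dists(b, a))) /
    (nrow(a) + nrow(b))
}

brute_boundary <- function(mask, spacing = 1) {
  pts <- NULL
  H <- nrow(mask); W <- ncol(mask)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] == 0) next
    nb <- c(if (i > 1) mask[i - 1, j] else 0,
            if (i < H) mask[i + 1, j] else 0,
            if (j > 1) mask[i, j - 1] else 0,
            if (j < W) mask[i, j + 1] else 0)
    if (any(nb == 0)) pts <- rbind(pts, c(i - 1, j - 1) * spacing)
  }
  pts
}

# naive O(n^2) scaled dot-product attention on (H, W, C) arrays
brute_attention <- function(q, k, v) {
  H <- dim(q)[1]; W <- dim(q)[2]; C <- dim(q)[3]
  n <- H * W
  Qm <- matrix(aperm(array(q, dim = c(H, W, C, 1)), c(1, 2, 4, 3)), n, C)
  Km <- matrix(aperm(array(k, dim = c(H, W, C, 1)), c(1, 2, 4, 3)), n, C)
  Vm <- matrix(aperm(array(v, dim = c(H, W, C, 1)), c(1, 2, 4, 3)), n, C)
  O <- matrix(0, n, C)
  for (i in seq_len(n)) {
    s <- numeric(n)
    for (j in seq_len(n)) s[j] <- sum(Qm[i, ] * Km[j, ]) / sqrt(C)
    w <- exp(s - max(s))
    w <- w / sum(w)
    for (j in seq_len(n)) O[i, ] <- O[i, ] + w[j] * Vm[j, ]
  }
  array(aperm(array(O, dim = c(H, W, 1, C)), c(1, 2, 4, 3)), dim = c(H, W, C))
}

random_mask <- function(H, W, p = 0.4) {
  matrix(as.integer(runif(H * W) < p), H, W)
}

# small, fast phantom config for training-path tests
tiny_phantom_config <- function(size = 32L) {
  phantom_config(image_size_px = size, pixel_spacing_mm = 50 / size * 1.28,
                 notch_width_mm_range = c(5, 8), femur_diameter_mm = 50,
                 notch_depth_mm_range = c(32, 37))
}

tiny_network_config <- function(...) {
  network_config(stage_channels = c(4L, 8L, 12L, 16L), input_size_px = 32L, ...)
}

# center-tap identity weights for a depthwise kernel (k, k, C)
identity_dw <- function(k, C) {
  w <- array(0, dim = c(k, k, C))
  w[(k + 1) / 2, (k + 1) / 2, ] <- 1
  w
}

# identity 1x1 convolution weights (1, 1, C, C)
identity_pw <- function(C) {
  w <- array(0, dim = c(1, 1, C, C))
  for (i in seq_len(C)) w[1, 1, i, i] <- 1
  w
}
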