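# Training-time augmentation: random rotation, horizontal flipping, and
# elastic deformation. One geometric transform is sampled per call and
# applied identically to the image (bilinear interpolation) and the mask
# (nearest-neighbour, so no new labels can appear).

#' Augmentation configuration
#'
#' @param rotation_deg maximum absolute rotation angle (degrees); the angle
#'   is drawn uniformly from `[-rotation_deg, rotation_deg]`.
#' @param hflip_prob probability of a horizontal flip.
#' @param elastic_alpha elastic displacement scale (default 800): random
#'   unit fields are Gaussian-smoothed, then multiplied by `alpha`.
#' @param elastic_sigma smoothing sigma of the elastic fields in px
#'   (default 20).
#' @param enabled master switch; when `FALSE`, [augment()] is a pass-through.
#' @return an `augment_config` list.
#' @export
augment_config <- function(rotation_deg = 15, hflip_prob = 0.5,
                           elastic_alpha = 800, elastic_sigma = 20,
                           enabled = TRUE) {
  if (rotation_deg < 0 || hflip_prob < 0 || hflip_prob > 1 ||
      elastic_alpha < 0 || elastic_sigma < 0) {
    stop("augmentation magnitudes must be nonnegative (hflip_prob in [0, 1])")
  }
  structure(list(rotation_deg = rotation_deg, hflip_prob = hflip_prob,
                 elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma,
                 enabled = enabled), class = "augment_config")
}

# bilinear / nearest sampling at fractional source coordinates, constant
# fill outside the frame
sample_at <- function(img, sy, sx, method = c("bilinear", "nearest"), fill = 0) {
  method <- match.arg(method)
  H <- nrow(img); W <- ncol(img)
  if (method == "nearest") {
    ry <- round(sy); rx <- round(sx)
    ok <- ry >= 1 & ry <= H & rx >= 1 & rx <= W
    out <- matrix(fill, H, W)
    out[ok] <- img[cbind(ry[ok], rx[ok])]
    return(out)
  }
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  gather <- function(yy, xx) {
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    v <- matrix(fill, H, W)
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  v00 <- gather(y0, x0); v01 <- gather(y0, x0 + 1)
  v10 <- gather(y0 + 1, x0); v11 <- gather(y0 + 1, x0 + 1)
  v00 * (1 - fy) * (1 - fx) + v01 * (1 - fy) * fx +
    v10 * fy * (1 - fx) + v11 * fy * fx
}

gaussian_blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  padded <- m[pmin(pmax(seq(1 - r, H + r), 1), H), , drop = FALSE]
  m2 <- apply(padded, 2, function(v) stats::filter(v, k, sides = 2))[r + seq_len(H), , drop = FALSE]
  padded <- m2[, pmin(pmax(seq(1 - r, W + r), 1), W), drop = FALSE]
  t(apply(padded, 1, function(v) stats::filter(v, k, sides = 2)))[, r + seq_len(W), drop = FALSE]
}

#' Flip a sample horizontally
#'
#' Mirrors image and mask about the vertical axis; applying it twice
#' restores the original sample.
#'
#' @param sample an `image_sample`.
#' @return the flipped sample.
#' @export
flip_horizontal <- function(sample) {
  sample$image <- sample$image[, ncol(sample$image):1]
  sample$mask <- sample$mask[, ncol(sample$mask):1]
  sample
}

#' Randomly augment a sample
#'
#' Samples one transform (rotation in `[-rotation_deg, rotation_deg]` about
#' the image centre, horizontal flip with `hflip_prob`, elastic
#' displacement fields smoothed with `elastic_sigma` and scaled by
#' `elastic_alpha`) and applies it to image and mask with bilinear /
#' nearest-neighbour interpolation respectively, so the mask's label set
#' can only shrink. Uses the current RNG stream unless `seed` is given.
#'
#' @param sample an `image_sample`.
#' @param cfg an [augment_config()].
#' @param seed optional seed for a reproducible transform.
#' @return the augmented `image_sample`.
#' @export
augment <- function(sample, cfg = augment_config(), seed = NULL) {
  if (!cfg$enabled) return(sample)
  if (!is.null(seed)) return(local_seed(seed, augment(sample, cfg)))
  img <- sample$image
  H <- nrow(img); W <- ncol(img)

  if (stats::runif(1) < cfg$hflip_prob) sample <- flip_horizontal(sample)

  theta <- stats::runif(1, -cfg$rotation_deg, cfg$rotation_deg) * pi / 180
  dx_field <- gaussian_blur_matrix(matrix(stats::runif(H * W, -1, 1), H, W),
                                   cfg$elastic_sigma) * cfg$elastic_alpha
  dy_field <- gaussian_blur_matrix(matrix(stats::runif(H * W, -1, 1), H, W),
                                   cfg$elastic_sigma) * cfg$elastic_alpha

  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  row <- matrix(seq_len(H), H, W)
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  # inverse rotation: target -> source
  sy <- cy + cos(theta) * (row - cy) - sin(theta) * (col - cx) + dy_field
  sx <- cx + sin(theta) * (row - cy) + cos(theta) * (col - cx) + dx_field

  bg <- sample$image[1, 1]
  sample$image <- sample_at(sample$image, sy, sx, "bilinear", fill = bg)
  sample$mask <- matrix(as.integer(sample_at(sample$mask, sy, sx, "nearest",
                                             fill = 0)), H, W)
  sample
}
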