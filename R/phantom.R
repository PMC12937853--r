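# Synthetic knee-slice phantoms. The binary task emulates a sagittal view of
# the distal femur: a bright bone disc with a narrow, concave intercondylar
# notch (5-8 mm wide) cut into its distal margin, a near-isointense
# distractor tissue adjacent to the notch opening (emulating scar tissue
# with < 10% signal difference), blurred bone-soft-tissue interfaces, and
# additive Gaussian noise. Roughly 30% of samples carry an osteophyte-like
# bony protrusion deforming the notch contour. The 5-class task adds tibia,
# meniscus and cruciate-ligament structures.

local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Phantom generator configuration
#'
#' Defaults reproduce the anatomical envelope of the segmentation task: a
#' femur-like disc of about 50 mm diameter holding a concave notch 5-8 mm
#' wide whose pixel area averages a mid-single-digit percentage of the
#' frame, a distractor tissue within `distractor_contrast` of the notch
#' intensity, blurred boundaries, and osteophyte-like deformations in about
#' 30% of samples.
#'
#' @param image_size_px square image side in pixels.
#' @param pixel_spacing_mm physical pixel size in mm (default 0.5).
#' @param notch_width_mm_range closed interval the per-sample notch width is
#'   drawn from (default `c(5, 8)` mm).
#' @param femur_diameter_mm nominal femur diameter (default 50 mm); the
#'   per-sample diameter is drawn within a few percent below it.
#' @param notch_depth_mm_range interval the notch depth is drawn from
#'   (default `c(32, 37)` mm; together with the width range this places the
#'   mean notch area in the 5-8% band of frame pixels).
#' @param boundary_blur_sigma_px Gaussian blur applied to the rendered
#'   intensities (default 1.5 px), emulating partial-volume boundary blur.
#' @param noise_sd additive Gaussian noise standard deviation as a fraction
#'   of the intensity range (default 0.03).
#' @param distractor_contrast maximum intensity gap between the distractor
#'   tissue and the notch (default 0.05; must lie in `[0, 0.1]`).
#' @param osteophyte_probability probability of an osteophyte-like
#'   protrusion on the notch contour (default 0.3).
#' @param n_classes 2 (binary notch task) or 5 (knee task).
#' @param intensities named list of rendering intensities
#'   (`background`, `bone`, `notch`, `meniscus`, `ligament`).
#' @return a validated `phantom_config` list.
#' @export
phantom_config <- function(image_size_px = 112L,
                           pixel_spacing_mm = 0.5,
                           notch_width_mm_range = c(5, 8),
                           femur_diameter_mm = 50,
                           notch_depth_mm_range = c(32, 37),
                           boundary_blur_sigma_px = 1.5,
                           noise_sd = 0.03,
                           distractor_contrast = 0.05,
                           osteophyte_probability = 0.3,
                           n_classes = 2L,
                           intensities = list(background = 0.15, bone = 0.85,
                                              notch = 0.45, meniscus = 0.35,
                                              ligament = 0.45)) {
  cfg <- list(image_size_px = as.integer(image_size_px),
              pixel_spacing_mm = pixel_spacing_mm,
              notch_width_mm_range = notch_width_mm_range,
              femur_diameter_mm = femur_diameter_mm,
              notch_depth_mm_range = notch_depth_mm_range,
              boundary_blur_sigma_px = boundary_blur_sigma_px,
              noise_sd = noise_sd,
              distractor_contrast = distractor_contrast,
              osteophyte_probability = osteophyte_probability,
              n_classes = as.integer(n_classes),
              intensities = intensities)
  validate_phantom_config(cfg)
  class(cfg) <- "phantom_config"
  cfg
}

validate_phantom_config <- function(cfg) {
  err <- function(...) stop("configuration error: ", ..., call. = FALSE)
  if (cfg$image_size_px < 1) err("image_size_px must be positive")
  if (cfg$pixel_spacing_mm <= 0) err("pixel_spacing_mm must be positive")
  r <- cfg$notch_width_mm_range
  if (length(r) != 2 || r[1] <= 0 || r[1] > r[2]) {
    err("notch_width_mm_range lower bound must be > 0 and <= upper bound")
  }
  if (cfg$femur_diameter_mm < r[2]) {
    err("femur_diameter_mm must be >= the notch width upper bound")
  }
  if (cfg$image_size_px * cfg$pixel_spacing_mm < cfg$femur_diameter_mm) {
    err("image_size_px * pixel_spacing_mm must be >= femur_diameter_mm ",
        "(the femur must fit in frame)")
  }
  if (cfg$boundary_blur_sigma_px < 0) err("boundary_blur_sigma_px must be nonnegative")
  if (cfg$noise_sd < 0) err("noise_sd must be nonnegative")
  if (cfg$distractor_contrast < 0 || cfg$distractor_contrast > 0.1) {
    err("distractor_contrast must lie in [0, 0.1]")
  }
  if (cfg$osteophyte_probability < 0 || cfg$osteophyte_probability > 1) {
    err("osteophyte_probability must lie in [0, 1]")
  }
  if (!cfg$n_classes %in% c(2L, 5L)) err("n_classes must be 2 or 5")
  d <- cfg$notch_depth_mm_range
  if (length(d) != 2 || d[1] <= 0 || d[1] > d[2]) {
    err("notch_depth_mm_range lower bound must be > 0 and <= upper bound")
  }
  invisible(cfg)
}

new_image_sample <- function(image, mask, spacing, provenance) {
  structure(list(image = image, mask = mask, pixel_spacing_mm = spacing,
                 provenance = provenance), class = "image_sample")
}

render_phantom_image <- function(base, blur_sigma, noise_sd) {
  img <- base
  if (blur_sigma > 0) {
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_sigma))
  }
  if (noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), sd = noise_sd),
                        nrow(img), ncol(img))
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a binary notch phantom
#'
#' Draws one synthetic slice: a bright femur-like disc with a concave notch
#' (one of three contour templates emulating a-, u- and w-shaped fossae) cut
#' into its distal margin, an adjacent near-isointense distractor blob, an
#' osteophyte-like protrusion with the configured probability, boundary
#' blur, and additive noise. Identical `(config, seed)` pairs give
#' bit-identical samples; the caller's RNG state is untouched.
#'
#' @param config a [phantom_config()] with `n_classes = 2`.
#' @param seed integer seed for this sample.
#' @return an `image_sample`: list with `image` (matrix in `[0, 1]`), `mask`
#'   (integer matrix, 1 = notch), `pixel_spacing_mm`, and a `provenance`
#'   record of the sampled geometry.
#' @export
generate_notch_phantom <- function(config, seed) {
  validate_phantom_config(config)
  if (config$n_classes != 2L) {
    stop("configuration error: generate_notch_phantom requires n_classes = 2")
  }
  local_seed(seed, {
    S <- config$image_size_px
    sp <- config$pixel_spacing_mm
    ints <- config$intensities

    d_mm <- config$femur_diameter_mm * stats::runif(1, 0.96, 1.0)
    r <- d_mm / sp / 2
    cy <- (S + 1) / 2
    slack <- max(0, S / 2 - r - 1)
    cx <- (S + 1) / 2 + stats::runif(1, -1, 1) * min(2, slack)

    row <- matrix(seq_len(S), S, S)
    col <- matrix(seq_len(S), S, S, byrow = TRUE)
    disc <- (row - cy)^2 + (col - cx)^2 <= r^2

    w_mm <- stats::runif(1, config$notch_width_mm_range[1],
                         config$notch_width_mm_range[2])
    depth_mm <- stats::runif(1, config$notch_depth_mm_range[1],
                             config$notch_depth_mm_range[2])
    w <- w_mm / sp
    depth <- depth_mm / sp
    xc <- cx + stats::runif(1, -2, 2)
    y_bot <- cy + r
    y_apex <- y_bot - depth
    notch_type <- sample(c("a", "u", "w"), 1)

    rel <- pmax(row - y_apex, 0)
    hw <- switch(notch_type,
      a = (w / 2) * pmin(1, rel / (0.5 * depth)),
      u = (w / 2) * sqrt(pmin(1, rel / pmax(w / 2, 1))),
      w = (w / 2) * sqrt(pmin(1, rel / pmax(w / 2, 1)))
    )
    notch <- disc & row >= y_apex & abs(col - xc) <= hw
    if (notch_type == "w") {
      ridge <- abs(col - xc) < w / 6 & rel < 0.25 * depth
      notch <- notch & !ridge
    }

    has_osteo <- stats::runif(1) < config$osteophyte_probability
    if (has_osteo) {
      side <- sample(c(-1, 1), 1)
      y_o <- stats::runif(1, y_apex + 0.3 * depth, y_bot - 0.2 * depth)
      x_o <- xc + side * (w / 2)
      r_o <- stats::runif(1, 1, 3) / sp
      osteo <- (row - y_o)^2 + (col - x_o)^2 <= r_o^2
      notch <- notch & !osteo
    }

    # distractor: soft-tissue blob just distal to the notch opening,
    # outside the femur, nearly isointense with the notch
    di <- ints$notch + config$distractor_contrast * stats::runif(1, -1, 1)
    dy <- y_bot + stats::runif(1, 2, 4)
    rx <- (w / 2) * stats::runif(1, 0.9, 1.3)
    ry <- stats::runif(1, 3, 6)
    distractor <- !disc &
      ((row - dy) / ry)^2 + ((col - xc) / rx)^2 <= 1

    base <- matrix(ints$background, S, S)
    base[disc] <- ints$bone
    base[notch] <- ints$notch
    base[distractor] <- di

    img <- render_phantom_image(base, config$boundary_blur_sigma_px,
                                config$noise_sd)
    mask <- matrix(0L, S, S)
    mask[notch] <- 1L

    new_image_sample(img, mask, sp, list(
      seed = seed, notch_width_mm = w_mm, notch_depth_mm = depth_mm,
      femur_diameter_mm = d_mm, notch_type = notch_type,
      has_osteophyte = has_osteo, notch_intensity = ints$notch,
      distractor_intensity = di, distractor_px = which(distractor),
      notch_px = which(notch)))
  })
}

#' Generate a 5-class knee phantom
#'
#' Draws one synthetic slice with all five labels: background (0), femur
#' (1) and tibia (2) as large bright bone regions, and meniscus (3) and
#' cruciate ligament (4) as thin low-contrast soft-tissue structures in the
#' joint space between them.
#'
#' @param config a [phantom_config()] with `n_classes = 5`.
#' @param seed integer seed for this sample.
#' @return an `image_sample` with labels `{0, ..., 4}` all present.
#' @export
generate_knee_phantom <- function(config, seed) {
  validate_phantom_config(config)
  if (config$n_classes != 5L) {
    stop("configuration error: generate_knee_phantom requires n_classes = 5")
  }
  local_seed(seed, {
    S <- config$image_size_px
    ints <- config$intensities
    row <- matrix(seq_len(S), S, S)
    col <- matrix(seq_len(S), S, S, byrow = TRUE)

    jit <- function(a, b) stats::runif(1, a, b) * S
    # femur above, tibia below, with a guaranteed joint gap between
    # (femur bottom <= 0.55 S, tibia top >= 0.62 S)
    fc <- c(jit(0.26, 0.30), jit(0.48, 0.52))      # femur centre (row, col)
    fr <- jit(0.22, 0.25)
    femur <- (row - fc[1])^2 + (col - fc[2])^2 <= fr^2

    tc <- c(jit(1.06, 1.12), jit(0.48, 0.52))      # tibia: big disc from below
    tr <- jit(0.40, 0.44)
    tibia <- (row - tc[1])^2 + (col - tc[2])^2 <= tr^2 & !femur

    gap_y <- jit(0.57, 0.60)
    men_off <- jit(0.24, 0.28)
    meniscus <- matrix(FALSE, S, S)
    for (s in c(-1, 1)) {
      mc <- c(gap_y, fc[2] + s * men_off)
      meniscus <- meniscus |
        ((row - mc[1]) / (0.04 * S))^2 + ((col - mc[2]) / (0.07 * S))^2 <= 1
    }
    meniscus <- meniscus & !femur & !tibia

    # cruciate ligament: oblique band through the joint space
    p1 <- c(jit(0.50, 0.53), jit(0.55, 0.58))
    p2 <- c(jit(0.66, 0.70), jit(0.42, 0.46))
    v <- p2 - p1
    tpar <- ((row - p1[1]) * v[1] + (col - p1[2]) * v[2]) / sum(v^2)
    dperp <- sqrt((row - (p1[1] + tpar * v[1]))^2 +
                  (col - (p1[2] + tpar * v[2]))^2)
    ligament <- dperp <= 0.03 * S & tpar >= 0 & tpar <= 1 &
      !femur & !tibia & !meniscus

    mask <- matrix(0L, S, S)
    mask[femur] <- 1L
    mask[tibia] <- 2L
    mask[meniscus] <- 3L
    mask[ligament] <- 4L
    if (!all(0:4 %in% mask)) {
      stop("internal geometry error: a structure was clipped away (seed ",
           seed, ")")
    }

    base <- matrix(ints$background, S, S)
    base[femur | tibia] <- ints$bone
    base[meniscus] <- ints$meniscus
    base[ligament] <- ints$ligament
    img <- render_phantom_image(base, config$boundary_blur_sigma_px,
                                config$noise_sd)

    new_image_sample(img, mask, config$pixel_spacing_mm,
                     list(seed = seed, femur_centre = fc, femur_radius = fr))
  })
}

#' Measure phantom geometry
#'
#' Reads physical geometry back from a binary notch sample: the maximal
#' horizontal extent of the notch label at its widest row (in mm), the
#' fraction of notch-labelled pixels, and the femur diameter obtained by
#' thresholding the image at the bone/soft-tissue midpoint intensity,
#' keeping the largest connected component, and taking its maximal axis
#' extent.
#'
#' @param sample an `image_sample` whose mask contains the notch label (1).
#' @return a `phantom_geometry` list: `notch_width_mm`,
#'   `notch_area_fraction`, `femur_diameter_mm`, `has_osteophyte`.
#' @export
measure_phantom <- function(sample) {
  mask <- sample$mask
  sp <- sample$pixel_spacing_mm
  if (!any(mask == 1L)) {
    stop("measurement error: mask contains no notch-labelled pixels")
  }
  width_px <- max(vapply(seq_len(nrow(mask)), function(i) {
    cols <- which(mask[i, ] == 1L)
    if (length(cols) == 0L) 0L else diff(range(cols)) + 1L
  }, 0L))

  bright <- sample$image > 0.5
  lab <- EBImage::bwlabel(EBImage::Image(bright * 1))
  labm <- as.matrix(lab)
  if (max(labm) < 1) stop("measurement error: no bright femur region found")
  counts <- tabulate(labm[labm > 0])
  femur <- labm == which.max(counts)
  rows <- range(which(rowSums(femur) > 0))
  cols <- range(which(colSums(femur) > 0))
  diam_px <- max(diff(rows) + 1L, diff(cols) + 1L)

  structure(list(
    notch_width_mm = width_px * sp,
    notch_area_fraction = sum(mask == 1L) / length(mask),
    femur_diameter_mm = diam_px * sp,
    has_osteophyte = isTRUE(sample$provenance$has_osteophyte)
  ), class = "phantom_geometry")
}
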