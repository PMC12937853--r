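# Dataset writing/reading. Images: 8-bit grayscale PNG (quantization 1/255,
# far below phantom noise levels) or float32 single-slice NIfTI. Masks:
# 8-bit PNG storing raw label values 0..4 (lossless).

write_image_sample <- function(sample, stem, format = c("png", "nifti")) {
  format <- match.arg(format)
  msk_path <- paste0(stem, "_msk.png")
  png::writePNG(sample$mask / 255, msk_path)
  if (format == "png") {
    img_path <- paste0(stem, "_img.png")
    png::writePNG(pmin(pmax(sample$image, 0), 1), img_path)
  } else {
    img_path <- paste0(stem, "_img.nii.gz")
    RNifti::writeNifti(
      RNifti::asNifti(sample$image,
                      pixdim = c(sample$pixel_spacing_mm,
                                 sample$pixel_spacing_mm, 1)),
      img_path, datatype = "float")
  }
  invisible(c(image = img_path, mask = msk_path))
}

read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Read an image/mask pair written by [generate_dataset()]
#'
#' @param stem file stem (paths `<stem>_img.png` or `<stem>_img.nii.gz` and
#'   `<stem>_msk.png`).
#' @param pixel_spacing_mm physical pixel spacing of the sample.
#' @return an `image_sample`.
#' @export
read_image_sample <- function(stem, pixel_spacing_mm = 0.5) {
  img_png <- paste0(stem, "_img.png")
  if (file.exists(img_png)) {
    img <- png::readPNG(img_png)
    if (length(dim(img)) == 3L) img <- img[, , 1]
  } else {
    nii <- RNifti::readNifti(paste0(stem, "_img.nii.gz"))
    img <- matrix(as.numeric(nii), dim(nii)[1], dim(nii)[2])
  }
  mask <- read_mask_png(paste0(stem, "_msk.png"))
  new_image_sample(img, mask, pixel_spacing_mm, list(stem = stem))
}

#' Generate and write a phantom dataset
#'
#' Writes `n` image/mask pairs under `out_dir` (stems `sample_0001`, ...)
#' with deterministic per-sample seeds `seed + 1 .. seed + n`, plus a
#' `manifest.csv` listing the file stem, per-sample seed, and the geometry
#' report measured from the files as written (so manifest entries equal
#' [measure_phantom()] re-applied to a re-read sample). Re-running with the
#' same arguments reproduces identical files.
#'
#' @param config a [phantom_config()].
#' @param n number of samples (>= 1).
#' @param seed base seed.
#' @param out_dir output directory (created if needed).
#' @param format `"png"` (8-bit) or `"nifti"` (float32 image).
#' @return the manifest as a data.frame, invisibly also written to
#'   `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(config, n, seed, out_dir,
                             format = c("png", "nifti")) {
  format <- match.arg(format)
  if (n < 1L) stop("n must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create ", out_dir)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    si <- seed + i
    sample <- if (config$n_classes == 2L) {
      generate_notch_phantom(config, si)
    } else {
      generate_knee_phantom(config, si)
    }
    stem <- file.path(out_dir, sprintf("sample_%04d", i))
    write_image_sample(sample, stem, format)
    reread <- read_image_sample(stem, config$pixel_spacing_mm)
    reread$provenance <- sample$provenance
    if (config$n_classes == 2L) {
      g <- measure_phantom(reread)
      rows[[i]] <- data.frame(stem = basename(stem), seed = si,
                              notch_width_mm = g$notch_width_mm,
                              notch_area_fraction = g$notch_area_fraction,
                              femur_diameter_mm = g$femur_diameter_mm,
                              has_osteophyte = g$has_osteophyte)
    } else {
      rows[[i]] <- data.frame(stem = basename(stem), seed = si,
                              notch_width_mm = NA_real_,
                              notch_area_fraction = NA_real_,
                              femur_diameter_mm = NA_real_,
                              has_osteophyte = NA)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
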