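# Synthetic phantom generator: determinism, geometry, contrast, and I/O.

test_that("identical config and seed give bit-identical samples", {
  cfg <- phantom_config()
  a <- generate_notch_phantom(cfg, 7)
  b <- generate_notch_phantom(cfg, 7)
  expect_identical(a, b)
  expect_false(identical(a$image, generate_notch_phantom(cfg, 8)$image))

  cfg5 <- phantom_config(n_classes = 5)
  expect_identical(generate_knee_phantom(cfg5, 3), generate_knee_phantom(cfg5, 3))

  # the caller's RNG stream is untouched
  set.seed(99); r1 <- runif(1)
  set.seed(99); invisible(generate_notch_phantom(cfg, 1)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("configuration invariants are enforced with named errors", {
  expect_error(phantom_config(notch_width_mm_range = c(0, 8)), "lower bound")
  expect_error(phantom_config(notch_width_mm_range = c(9, 8)), "lower bound")
  expect_error(phantom_config(femur_diameter_mm = 6), "notch width upper bound")
  expect_error(phantom_config(image_size_px = 50, pixel_spacing_mm = 0.5),
               "fit in frame")
  expect_error(phantom_config(distractor_contrast = 0.2), "distractor_contrast")
  expect_error(phantom_config(osteophyte_probability = 1.5), "osteophyte")
  expect_error(phantom_config(n_classes = 3), "n_classes")
  expect_error(generate_notch_phantom(phantom_config(n_classes = 5), 1),
               "n_classes = 2")
  expect_error(generate_knee_phantom(phantom_config(), 1), "n_classes = 5")
})

test_that("without noise or blur the notch interior is exactly its intensity", {
  cfg <- phantom_config(noise_sd = 0, boundary_blur_sigma_px = 0)
  s <- generate_notch_phantom(cfg, 1)
  expect_true(all(s$image[s$mask == 1L] == cfg$intensities$notch))
  expect_true(all(s$image >= 0 & s$image <= 1))
})

test_that("masks contain only valid labels across random configs and seeds", {
  set.seed(61)
  for (i in 1:150) {
    n_classes <- sample(c(2L, 5L), 1)
    size <- sample(c(64L, 80L, 112L), 1)
    cfg <- phantom_config(image_size_px = size,
                          pixel_spacing_mm = 50 / size * runif(1, 1.02, 1.4),
                          noise_sd = runif(1, 0, 0.06),
                          boundary_blur_sigma_px = runif(1, 0, 2),
                          distractor_contrast = runif(1, 0, 0.1),
                          osteophyte_probability = runif(1),
                          n_classes = n_classes)
    s <- if (n_classes == 2L) generate_notch_phantom(cfg, i) else
      generate_knee_phantom(cfg, i)
    expect_true(all(s$mask %in% 0:(n_classes - 1L)))
    expect_identical(dim(s$image), dim(s$mask))
    expect_true(all(s$image >= 0 & s$image <= 1))
  }
})

test_that("default-config geometry stays in the anatomical envelope", {
  cfg <- phantom_config()
  geoms <- lapply(1:200, function(s) measure_phantom(generate_notch_phantom(cfg, s)))
  widths <- vapply(geoms, `[[`, 0, "notch_width_mm")
  areas <- vapply(geoms, `[[`, 0, "notch_area_fraction")
  tol <- cfg$pixel_spacing_mm
  expect_true(all(widths >= cfg$notch_width_mm_range[1] - tol &
                  widths <= cfg$notch_width_mm_range[2] + tol))
  expect_gte(mean(areas), 0.05)
  expect_lte(mean(areas), 0.08)
})

test_that("knee phantoms carry all five labels with femur dominating meniscus", {
  cfg <- phantom_config(n_classes = 5)
  s3 <- generate_knee_phantom(cfg, 3)
  expect_setequal(unique(as.integer(s3$mask)), 0:4)
  for (seed in 1:50) {
    m <- generate_knee_phantom(cfg, seed)$mask
    expect_gt(sum(m == 1L), sum(m == 3L))
  }
})

test_that("distractor intensity honours the contrast contract", {
  for (c in c(0, 0.03, 0.1)) {
    for (noise in c(0, 0.02)) {
      cfg <- phantom_config(distractor_contrast = c, noise_sd = noise,
                            boundary_blur_sigma_px = 0)
      s <- generate_notch_phantom(cfg, 11)
      d_px <- s$provenance$distractor_px
      n_px <- s$provenance$notch_px
      gap <- abs(mean(s$image[d_px]) - mean(s$image[n_px]))
      allowance <- 3 * noise / sqrt(min(length(d_px), length(n_px)))
      expect_lte(gap, c + allowance + 1e-12)
    }
  }
})

test_that("measure_phantom reads geometry exactly from hand-built samples", {
  mask <- matrix(0L, 20, 20)
  mask[5:9, 6:15] <- 1L                      # 10-px-wide rectangle
  img <- matrix(0, 20, 20); img[2:18, 2:18] <- 0.9
  s <- structure(list(image = img, mask = mask, pixel_spacing_mm = 0.5,
                      provenance = list()), class = "image_sample")
  g <- measure_phantom(s)
  expect_equal(g$notch_width_mm, 5.0)        # 10 px x 0.5 mm
  expect_equal(g$femur_diameter_mm, 17 * 0.5)
  expect_false(g$has_osteophyte)

  mask16 <- matrix(0L, 16, 16); mask16[sample(256, 13)] <- 1L
  s16 <- structure(list(image = img[1:16, 1:16], mask = mask16,
                        pixel_spacing_mm = 1, provenance = list()),
                   class = "image_sample")
  expect_equal(measure_phantom(s16)$notch_area_fraction, 13 / 256)

  s$mask <- matrix(0L, 20, 20)
  expect_error(measure_phantom(s), "measurement error")
})

test_that("datasets round-trip through files with a consistent manifest", {
  cfg <- phantom_config(image_size_px = 64, pixel_spacing_mm = 1,
                        notch_depth_mm_range = c(32, 37))
  out1 <- withr::local_tempdir()
  man <- generate_dataset(cfg, 4, seed = 0, out_dir = out1)
  expect_equal(nrow(man), 4)
  expect_equal(anyDuplicated(man$seed), 0)
  expect_true(all(file.exists(file.path(out1, paste0(man$stem, "_img.png")))))

  # manifest geometry equals measure_phantom on the re-read files
  for (i in seq_len(4)) {
    s <- read_image_sample(file.path(out1, man$stem[i]), cfg$pixel_spacing_mm)
    g <- measure_phantom(s)
    expect_equal(g$notch_width_mm, man$notch_width_mm[i])
    expect_equal(g$notch_area_fraction, man$notch_area_fraction[i])
    expect_equal(g$femur_diameter_mm, man$femur_diameter_mm[i])
  }

  # re-running reproduces identical files
  out2 <- withr::local_tempdir()
  man2 <- generate_dataset(cfg, 4, seed = 0, out_dir = out2)
  expect_equal(man[names(man) != "stem"], man2[names(man2) != "stem"])
  f1 <- file.path(out1, paste0(man$stem[1], "_img.png"))
  f2 <- file.path(out2, paste0(man2$stem[1], "_img.png"))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # NIfTI image dialect round-trips too
  out3 <- withr::local_tempdir()
  man3 <- generate_dataset(cfg, 2, seed = 5, out_dir = out3, format = "nifti")
  s3 <- read_image_sample(file.path(out3, man3$stem[1]), cfg$pixel_spacing_mm)
  ref <- generate_notch_phantom(cfg, 6)
  expect_equal(s3$image, ref$image, tolerance = 1e-6)
  expect_identical(s3$mask, ref$mask)
})
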