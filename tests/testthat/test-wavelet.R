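# Haar analysis/synthesis, soft thresholding, and the WSFB pathways.

test_that("Haar transform matches the closed-form 2x2 example and its conventions", {
  b <- haar_decompose(matrix(c(1, 3, 2, 4), 2, 2))  # [[1,2],[3,4]] row-wise
  expect_equal(as.numeric(b$ll), 5)
  expect_equal(as.numeric(b$lh), -2)
  expect_equal(as.numeric(b$hl), -1)
  expect_equal(as.numeric(b$hh), 0)

  # constant input has no detail energy
  bc <- haar_decompose(matrix(3.7, 8, 8))
  expect_true(all(abs(c(bc$lh, bc$hl, bc$hh)) < 1e-12))

  # pure approximation reconstructs to a constant c/2 per 2x2 block
  bands <- list(ll = matrix(4, 2, 2), lh = matrix(0, 2, 2),
                hl = matrix(0, 2, 2), hh = matrix(0, 2, 2))
  expect_equal(haar_reconstruct(bands), matrix(2, 4, 4))
})

test_that("decompose -> reconstruct is the identity and preserves energy", {
  set.seed(11)
  for (sz in c(4L, 8L, 16L, 32L, 64L)) {
    for (rep in 1:5) {
      x <- array(rnorm(sz * sz * 2), dim = c(sz, sz, 2))
      b <- haar_decompose(x)
      expect_lt(max(abs(haar_reconstruct(b) - x)), 1e-6)
      e_bands <- sum(vapply(b[c("ll", "lh", "hl", "hh")],
                            function(v) sum(v^2), 0))
      expect_lt(abs(e_bands - sum(x^2)) / sum(x^2), 1e-5)
    }
  }
})

test_that("odd-dimension inputs are reflect-padded and cropped back", {
  set.seed(3)
  x <- matrix(rnorm(7 * 9), 7, 9)
  b <- haar_decompose(x)
  expect_equal(dim(b$ll), c(4L, 5L))
  expect_lt(max(abs(haar_reconstruct(b) - x)), 1e-6)
})

test_that("soft threshold follows its definition and is monotone in t", {
  expect_equal(soft_threshold(0, 0.3), 0)
  expect_equal(soft_threshold(0.10, 0.05), 0.05)
  expect_equal(soft_threshold(-0.03, 0.05), 0)
  x <- matrix(rnorm(64), 8, 8)
  expect_equal(soft_threshold(x, 0), x)
  expect_error(soft_threshold(x, -0.1), "nonnegative")
  # |S(v, t1)| >= |S(v, t2)| whenever t1 <= t2
  ts <- sort(runif(5))
  for (i in 1:4) {
    expect_true(all(abs(soft_threshold(x, ts[i])) >=
                    abs(soft_threshold(x, ts[i + 1])) - 1e-12))
  }
})

test_that("high-frequency path thresholds, concatenates and convolves", {
  set.seed(5)
  x <- array(rnorm(16 * 16 * 2), dim = c(16, 16, 2))
  bands <- haar_decompose(x)

  # contract: output channels and spatial shape
  cfg <- wsfb_config(2L, fused_channels = 6L)
  fh <- highfreq_path(bands, cfg)
  expect_equal(dim(fh), c(8L, 8L, 6L))

  # frozen depthwise-identity conv units, normalization and activation off:
  # the path must return exactly the thresholded concatenated bands
  cfg_id <- wsfb_config(2L, fused_channels = 6L, norm = FALSE, act = "none")
  cfg_id$high1$w$value <- identity_pw(6L) |> (\(w) {
    wk <- array(0, dim = c(3, 3, 6, 6)); wk[2, 2, , ] <- w[1, 1, , ]; wk
  })()
  cfg_id$high1$b$value <- numeric(6)
  cfg_id$high2$w$value <- cfg_id$high1$w$value
  cfg_id$high2$b$value <- numeric(6)
  fh_id <- highfreq_path(bands, cfg_id)
  want <- array(0, dim = c(8, 8, 6))
  want[, , 1:2] <- soft_threshold(bands$lh, 0.05)
  want[, , 3:4] <- soft_threshold(bands$hl, 0.05)
  want[, , 5:6] <- soft_threshold(bands$hh, 0.05)
  expect_equal(fh_id, want, tolerance = 1e-12)

  # zero bands with zero biases propagate to zero
  zb <- lapply(bands, function(b) if (is.array(b)) b * 0 else b)
  class(zb) <- class(bands); attributes(zb) <- attributes(bands)
  expect_true(all(abs(highfreq_path(zb, cfg_id)) < 1e-12))
})

test_that("low-frequency path fuses ll with the encoder feature", {
  set.seed(6)
  cfg <- wsfb_config(2L, enc_channels = 3L, fused_channels = 5L)
  ll <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 2))
  enc <- array(rnorm(8 * 8 * 3), dim = c(8, 8, 3))
  fl <- lowfreq_path(ll, enc, cfg)
  expect_equal(dim(fl), c(8L, 8L, 5L))

  # spatial mismatch is bilinearly aligned to the encoder feature
  ll_big <- array(rnorm(16 * 16 * 2), dim = c(16, 16, 2))
  expect_equal(dim(lowfreq_path(ll_big, enc, cfg)), c(8L, 8L, 5L))

  # zero inputs with zero-bias projection give zero output
  cfg0 <- wsfb_config(2L, enc_channels = 3L, fused_channels = 5L,
                      norm = FALSE, act = "none")
  cfg0$low$b$value <- numeric(5)
  expect_true(all(abs(lowfreq_path(ll * 0, enc * 0, cfg0)) < 1e-12))
})

test_that("fusion aligns resolutions, compresses channels and is nonnegative", {
  set.seed(7)
  cfg <- wsfb_config(2L, fused_channels = 4L)
  fh <- array(rnorm(16 * 16 * 4), dim = c(16, 16, 4))
  fl <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4))
  out <- wsfb_fuse(fh, fl, cfg)
  expect_equal(dim(out), c(8L, 8L, 4L))
  expect_gte(min(out), 0)  # ReLU contract
  expect_error(wsfb_fuse(fl, fh, cfg), "shape error")

  # 1x1 kernel frozen to average-of-channels, zero bias: output equals
  # ReLU of the channel mean of the aligned concatenation
  cfg_avg <- wsfb_config(2L, fused_channels = 4L, norm = FALSE)
  cfg_avg$fuse$w$value <- array(1 / 8, dim = c(1, 1, 8, 4))
  cfg_avg$fuse$b$value <- numeric(4)
  out2 <- wsfb_fuse(fh, fl, cfg_avg)
  fh_dn <- (fh[seq(1, 15, 2), seq(1, 15, 2), ] + fh[seq(2, 16, 2), seq(1, 15, 2), ] +
            fh[seq(1, 15, 2), seq(2, 16, 2), ] + fh[seq(2, 16, 2), seq(2, 16, 2), ]) / 4
  mean_map <- apply(array(c(fh_dn, fl), dim = c(8, 8, 8)), c(1, 2), mean)
  want <- array(pmax(mean_map, 0), dim = c(8, 8, 1))[, , rep(1, 4)]
  expect_equal(out2, array(want, dim = c(8, 8, 4)), tolerance = 1e-12)
})

test_that("wsfb configuration validates its threshold", {
  expect_error(wsfb_config(2L, soft_threshold = -0.01), ">= 0")
})
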