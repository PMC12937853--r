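# SHFDEB dense detail extractor and the two multi-scale depth-wise blocks.

test_that("all blocks preserve shape across sizes and widths", {
  set.seed(21)
  for (sz in c(8L, 16L, 32L)) {
    for (ch in c(8L, 16L)) {
      x <- array(rnorm(sz * sz * ch), dim = c(sz, sz, ch))
      sh <- shfdeb_config(ch, growth_channels = 4L, n_layers = 2L,
                          out_channels = ch)
      expect_equal(dim(shfdeb_forward(x, sh, train = TRUE)), c(sz, sz, ch))
      mp <- mdcb_config(ch, variant = "parallel")
      expect_equal(dim(mdcb_parallel_forward(x, mp, train = TRUE)), dim(x))
      ms <- mdcb_config(ch, variant = "serial")
      expect_equal(dim(mdcb_serial_forward(x, ms, train = TRUE)), dim(x))
    }
  }
})

test_that("SHFDEB wiring follows dense-concat arithmetic", {
  cfg <- shfdeb_config(8L, growth_channels = 8L, n_layers = 2L)
  # second layer consumes in_channels + growth_channels channels
  expect_equal(dim(cfg$layers[[2]]$dw$w$value)[3], 16L)
  expect_equal(dim(cfg$layers[[2]]$pw$w$value)[3], 16L)
  expect_error(shfdeb_config(8L, n_layers = 1L), ">= 2")
  # channel mismatch is a shape error
  x <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4))
  expect_error(shfdeb_forward(x, cfg), "shape error")
})

test_that("SHFDEB convolution parameter count matches the closed form", {
  cfg <- shfdeb_config(8L, growth_channels = 8L, n_layers = 3L,
                       out_channels = 32L)
  # per dense layer: depthwise 3^2 * c_in + pointwise c_in * growth
  cins <- 8L + 8L * (0:2)
  expected <- sum(9L * cins + cins * 8L) + (8L + 3L * 8L) * 32L  # + projection
  params <- collect_params(cfg)
  conv_w <- params[grepl("\\.w$", names(params))]
  expect_equal(sum(vapply(conv_w, function(p) length(p$value), 0)), expected)
})

test_that("ablating a dense layer changes everything downstream", {
  set.seed(22)
  cfg <- shfdeb_config(4L, growth_channels = 4L, n_layers = 3L,
                       out_channels = 4L)
  x <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4))
  base <- shfdeb_forward(x, cfg, train = TRUE)
  for (j in 1:3) {
    old <- cfg$layers[[j]]$pw$w$value
    cfg$layers[[j]]$pw$w$value <- old * 0
    ablated <- shfdeb_forward(x, cfg, train = TRUE)
    expect_gt(max(abs(ablated - base)), 1e-8)
    cfg$layers[[j]]$pw$w$value <- old
  }
})

test_that("MDCB-P with identity-frozen kernels sums its branches plus residual", {
  set.seed(23)
  cfg <- mdcb_config(3L, kernel_sizes = c(3L, 5L, 7L), variant = "parallel",
                     norm = FALSE)
  for (i in seq_along(cfg$branches)) {
    cfg$branches[[i]]$w$value <- identity_dw(cfg$kernel_sizes[i], 3L)
  }
  cfg$mix$w$value <- identity_pw(3L)
  cfg$mix$b$value <- numeric(3)
  x <- array(runif(10 * 10 * 3) + 0.1, dim = c(10, 10, 3))  # positive input
  out <- mdcb_parallel_forward(x, cfg)
  expect_equal(out, 3 * x + x, tolerance = 1e-12)

  # zero input with zero biases stays zero
  expect_true(all(abs(mdcb_parallel_forward(x * 0, cfg)) < 1e-12))
  expect_error(mdcb_config(3L, kernel_sizes = c(3L, 4L)), "odd")
})

test_that("MDCB-S identity freeze doubles the input and its receptive field is 15", {
  set.seed(24)
  cfg <- mdcb_config(2L, kernel_sizes = c(7L, 9L), expansion = 1,
                     variant = "serial", norm = FALSE, act = "none")
  cfg$expand$w$value <- identity_pw(2L); cfg$expand$b$value <- numeric(2)
  cfg$project$w$value <- identity_pw(2L); cfg$project$b$value <- numeric(2)
  for (i in 1:2) cfg$dws[[i]]$w$value <- identity_dw(cfg$kernel_sizes[i], 2L)
  x <- array(rnorm(16 * 16 * 2), dim = c(16, 16, 2))
  expect_equal(mdcb_serial_forward(x, cfg), 2 * x, tolerance = 1e-12)

  # gradient-footprint probe: random linear kernels, delta input ->
  # response support is exactly the 15x15 theoretical receptive field
  cfg2 <- mdcb_config(1L, kernel_sizes = c(7L, 9L), expansion = 1,
                      variant = "serial", norm = FALSE, act = "none")
  cfg2$expand$w$value <- identity_pw(1L); cfg2$expand$b$value <- 0
  cfg2$project$w$value <- identity_pw(1L); cfg2$project$b$value <- 0
  for (i in 1:2) {
    cfg2$dws[[i]]$w$value <- array(runif(cfg2$kernel_sizes[i]^2, 0.1, 1),
                                   dim = c(cfg2$kernel_sizes[i],
                                           cfg2$kernel_sizes[i], 1))
  }
  delta <- array(0, dim = c(31, 31, 1)); delta[16, 16, 1] <- 1
  resp <- mdcb_serial_forward(delta, cfg2) - mdcb_serial_forward(delta * 0, cfg2)
  resp <- resp[, , 1] - delta[, , 1]  # remove the residual path
  hit <- which(abs(resp) > 1e-12, arr.ind = TRUE)
  expect_equal(range(hit[, 1]), c(16 - 7, 16 + 7))
  expect_equal(range(hit[, 2]), c(16 - 7, 16 + 7))
  expect_equal(1 + sum(c(7, 9) - 1), 15)
})
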