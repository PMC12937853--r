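# Saliency decomposition and the context-weighted attention module.

test_that("saliency decomposition follows its closed forms", {
  d5 <- decompose_saliency(0.5)
  expect_equal(c(d5$m_f, d5$m_b, d5$m_u), c(0, 0, 0.5))
  d8 <- decompose_saliency(0.8)
  expect_equal(c(d8$m_f, d8$m_b, d8$m_u), c(0.3, 0, 0.2))
  d2 <- decompose_saliency(0.2)
  expect_equal(c(d2$m_f, d2$m_b, d2$m_u), c(0, 0.3, 0.2))
  expect_error(decompose_saliency(c(0.2, 1.4)), "value error")
  expect_error(decompose_saliency(0.4, threshold = 1.2), "threshold")
})

test_that("decomposition identities hold over many random saliency values", {
  set.seed(31)
  f <- runif(1e5)
  d <- decompose_saliency(f)
  expect_lt(max(abs(d$m_f + d$m_b + d$m_u - 0.5)), 1e-12)
  expect_lt(max(abs(d$m_f * d$m_b)), 1e-12)
  # m_u attains its maximum exactly at the threshold
  g <- seq(0, 1, by = 1e-3)
  du <- decompose_saliency(g)$m_u
  expect_equal(g[which.max(du)], 0.5)
  expect_equal(max(du), 0.5)
})

test_that("uncertainty enhancement is exact elementwise addition", {
  set.seed(32)
  f <- matrix(runif(64), 8, 8)
  m_u <- matrix(runif(64, 0, 0.5), 8, 8)
  expect_equal(enhance_uncertain(f, matrix(0, 8, 8)), f)
  z <- matrix(0, 8, 8); m1 <- matrix(0, 8, 8); m1[3, 5] <- 0.5
  out <- enhance_uncertain(z, m1)
  expect_equal(out[3, 5], 0.5); expect_equal(sum(out), 0.5)
  expect_equal(enhance_uncertain(f, m_u) - f, m_u)
  # single-channel map broadcasts across channels
  f3 <- array(runif(64 * 3), dim = c(8, 8, 3))
  out3 <- enhance_uncertain(f3, m_u)
  for (c in 1:3) expect_equal(out3[, , c] - f3[, , c], m_u)
  expect_error(enhance_uncertain(f, matrix(0, 4, 4)), "shape error")
})

test_that("attention is a convex combination: constant values pass through, rows sum to 1", {
  set.seed(33)
  q <- array(rnorm(6 * 6 * 4), dim = c(6, 6, 4, 1))
  k <- array(rnorm(6 * 6 * 4), dim = c(6, 6, 4, 1))
  # V spatially constant per channel -> output equals that constant
  v <- array(rep(c(1.5, -2, 0.25, 7), each = 36), dim = c(6, 6, 4, 1))
  out <- wmcanet:::ag_no_grad(
    wmcanet:::ag_attention(wmcanet:::ag_const(q), wmcanet:::ag_const(k),
                           wmcanet:::ag_const(v)))$value
  for (c in 1:4) expect_equal(out[, , c, 1], matrix(v[1, 1, c, 1], 6, 6),
                              tolerance = 1e-10)
  # all-ones values recover the attention row sums, which must be exactly 1
  ones <- array(1, dim = c(6, 6, 4, 1))
  rs <- wmcanet:::ag_no_grad(
    wmcanet:::ag_attention(wmcanet:::ag_const(q), wmcanet:::ag_const(k),
                           wmcanet:::ag_const(ones)))$value
  expect_lt(max(abs(rs - 1)), 1e-12)
})

test_that("attention matches the brute-force double-loop oracle up to 8x8", {
  set.seed(34)
  for (sz in 2:8) {
    q <- array(rnorm(sz * sz * 3), dim = c(sz, sz, 3))
    k <- array(rnorm(sz * sz * 3), dim = c(sz, sz, 3))
    v <- array(rnorm(sz * sz * 3), dim = c(sz, sz, 3))
    fast <- wmcanet:::ag_no_grad(
      wmcanet:::ag_attention(wmcanet:::ag_const(wmcanet:::to4(q)),
                             wmcanet:::ag_const(wmcanet:::to4(k)),
                             wmcanet:::ag_const(wmcanet:::to4(v))))$value
    expect_lt(max(abs(fast[, , , 1] - brute_attention(q, k, v))), 1e-5)
  }
})

test_that("cwam gates a decoder feature and honours its contracts", {
  set.seed(35)
  cfg <- cwam_config(4L)
  f_m <- matrix(runif(16), 4, 4)
  f_l <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4))
  out <- cwam_forward(f_m, f_l, cfg)
  expect_equal(dim(out), dim(f_l))
  expect_error(cwam_forward(f_m * 4, f_l, cfg), "value error")
  f_bad <- f_l; f_bad[1] <- NA
  expect_error(cwam_forward(f_m, f_bad, cfg), "value error")

  # exceeding the token cap pools keys/values instead of erroring
  cfg_cap <- cwam_config(4L, attention_resolution_cap = 16L)
  out_cap <- cwam_forward(f_m, f_l, cfg_cap)
  expect_equal(dim(out_cap), dim(f_l))
  expect_gt(max(abs(out_cap - out)), 0)  # pooling genuinely changes the result
})

test_that("cwam output is equivariant to spatial token permutations", {
  set.seed(36)
  cfg <- cwam_config(3L)
  H <- 4L; W <- 4L
  f_m <- matrix(runif(H * W), H, W)
  f_l <- array(rnorm(H * W * 3), dim = c(H, W, 3))
  out <- cwam_forward(f_m, f_l, cfg)
  perm <- sample(H * W)
  permute <- function(a) {
    d <- dim(a)
    m <- matrix(a, H * W)
    array(m[perm, ], dim = d)
  }
  out_perm <- cwam_forward(permute(f_m), permute(f_l), cfg)
  expect_equal(out_perm, permute(out), tolerance = 1e-10)
})
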