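# Hybrid Dice + focal loss and class-weight computation.

test_that("dice loss matches hand-computed overlap cases", {
  y <- matrix(0L, 4, 4); y[1:2, 1:2] <- 1L
  p_perfect <- (y == 1) * 1
  expect_equal(dice_loss(p_perfect, y), 0)

  p_disjoint <- matrix(0, 4, 4); p_disjoint[3:4, 3:4] <- 1
  expect_equal(dice_loss(p_disjoint, y), 1)

  # |Y n Yhat| = 2, |Y| = |Yhat| = 4 -> 1 - 4/8 = 0.5
  y2 <- matrix(0L, 2, 4); y2[1, ] <- 1L          # 4 target pixels in row 1
  p2 <- matrix(0, 2, 4); p2[1, 1:2] <- 1; p2[2, 1:2] <- 1
  expect_equal(dice_loss(p2, y2), 0.5)

  # both-empty convention
  expect_equal(dice_loss(matrix(0, 3, 3), matrix(0L, 3, 3)), 0)
  expect_error(dice_loss(matrix(2, 3, 3), matrix(0L, 3, 3)), "value error")
})

test_that("focal loss matches the scalar hand calculation and its limits", {
  cfg <- loss_config(gamma = 2, epsilon = 1e-5)
  # single pixel, true-class probability 0.9:
  # -(0.1)^2 * log(0.90001) = 1.0535e-3
  p <- array(c(0.1, 0.9), dim = c(1, 1, 2))
  y <- matrix(1L, 1, 1)
  expect_equal(focal_loss(p, y, cfg), -(0.1)^2 * log(0.9 + 1e-5),
               tolerance = 1e-12)
  expect_equal(focal_loss(p, y, cfg), 1.0535e-3, tolerance = 1e-4)

  # perfectly confident prediction drives the loss to ~0
  p1 <- array(c(1e-9, 1 - 1e-9), dim = c(1, 1, 2))
  expect_lt(focal_loss(p1, y, cfg), 1e-12)

  # P = 0 stays finite thanks to epsilon: -log(epsilon)
  p0 <- array(c(1, 0), dim = c(1, 1, 2))
  expect_equal(focal_loss(p0, y, cfg), -log(1e-5), tolerance = 1e-9)

  # focal attenuation: a well-classified pixel contributes < 1/100 of a
  # hard one at gamma = 2
  easy <- focal_loss(array(c(0.05, 0.95), dim = c(1, 1, 2)), y, cfg)
  hard <- focal_loss(array(c(0.5, 0.5), dim = c(1, 1, 2)), y, cfg)
  expect_lt(easy / hard, 1 / 100)
})

test_that("hybrid loss is exactly bilinear in its weights", {
  set.seed(41)
  logits <- matrix(rnorm(64), 8, 8)
  y <- random_mask(8, 8)
  h10 <- hybrid_loss(logits, y, loss_config(alpha = 1, beta = 0))
  h01 <- hybrid_loss(logits, y, loss_config(alpha = 0, beta = 1))
  expect_equal(h10$total, h10$dice)
  expect_equal(h01$total, h01$focal)
  h55 <- hybrid_loss(logits, y, loss_config(alpha = 0.5, beta = 0.5))
  expect_equal(h55$total, 0.5 * h55$dice + 0.5 * h55$focal, tolerance = 1e-12)
  expect_equal(h55$dice, h10$dice)
  expect_equal(h55$focal, h01$focal)
  expect_error(loss_config(alpha = 0, beta = 0), "positive")
})

test_that("both loss components decrease towards the one-hot target", {
  set.seed(42)
  y <- random_mask(6, 6)
  target_p <- (y == 1) * 1
  cfg <- loss_config()
  for (path in 1:10) {
    start <- matrix(runif(36), 6, 6)
    lam <- seq(0, 0.98, length.out = 8)
    probs <- lapply(lam, function(l) (1 - l) * start + l * target_p)
    dvals <- vapply(probs, dice_loss, 0, target_mask = y)
    fvals <- vapply(probs, focal_loss, 0, target_mask = y, cfg = cfg)
    expect_true(all(diff(dvals) <= 1e-10))
    expect_true(all(diff(fvals) <= 1e-10))
    expect_true(all(dvals >= 0 & dvals <= 1))
    expect_true(all(fvals >= 0))
  }
})

test_that("multiclass dice averages over non-background classes", {
  y <- matrix(0L, 4, 4); y[1, ] <- 1L; y[2, ] <- 2L
  p <- array(0, dim = c(4, 4, 3))
  p[, , 1][y == 0] <- 1
  p[1, 1:2, 2] <- 1                        # half of class 1, no false positives
  p[, , 3][y == 2] <- 1                    # class 2 perfect
  d1 <- 1 - 2 * 2 / (2 + 4)
  expect_equal(dice_loss(p, y), mean(c(d1, 0)))
})

test_that("inverse-frequency class weights behave as specified", {
  m5050 <- matrix(c(0L, 1L), 10, 10)
  expect_equal(class_weights_from_frequencies(m5050, 2L), c(1, 1))

  m955 <- matrix(0L, 20, 20); m955[1:20] <- 1L  # 5% foreground
  w <- class_weights_from_frequencies(m955, 2L)
  expect_equal(w[2] / w[1], 0.95 / 0.05)
  expect_equal(mean(w), 1)

  mk <- matrix(0L, 10, 10); mk[1:30] <- 1L; mk[31:40] <- 2L; mk[41:44] <- 3L
  w5 <- class_weights_from_frequencies(mk, 5L)
  expect_equal(w5[5], max(w5[1:4]))               # absent class gets max weight
  # rarer present class has strictly larger weight
  expect_true(w5[4] > w5[3] && w5[3] > w5[2] && w5[2] > w5[1])
  expect_error(class_weights_from_frequencies(list(), 2L), "value error")
})
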