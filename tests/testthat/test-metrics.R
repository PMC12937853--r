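# Overlap and boundary-distance metrics against hand counts and brute force.

test_that("confusion counts match hand-enumerated cases", {
  y <- matrix(0L, 4, 4)
  y[1:2, 1:3] <- 1L; y[3, 1:4] <- 1L   # 10 target pixels
  p <- y
  cc <- confusion_counts(p, y)
  expect_equal(c(cc$fp, cc$fn), c(0L, 0L))

  inv <- 1L - y
  cc2 <- confusion_counts(inv, y)
  expect_equal(c(cc2$tp, cc2$tn), c(0L, 0L))

  # hand-built pair with tp=8, fp=2, fn=2, tn=4
  y3 <- matrix(0L, 4, 4); y3[1:2, ] <- 1L; y3[3, 1:2] <- 1L  # 10 positives
  p3 <- matrix(0L, 4, 4); p3[1:2, ] <- 1L                     # 8 tp
  p3[4, 1:2] <- 1L                                            # 2 fp
  cc3 <- confusion_counts(p3, y3)
  expect_equal(unclass(cc3), list(tp = 8L, fp = 2L, fn = 2L, tn = 4L))
  expect_equal(cc3$tp + cc3$fp + cc3$fn + cc3$tn, 16L)
  expect_equal(dsc(cc3), 16 / 20)
  expect_equal(iou(cc3), 8 / 12)
  expect_error(confusion_counts(matrix(0L, 2, 2), y3), "shape error")
})

test_that("iou = dsc / (2 - dsc) and dsc >= iou over random counts", {
  set.seed(51)
  counts <- data.frame(tp = sample(0:50, 1e4, TRUE), fp = sample(0:50, 1e4, TRUE),
                       fn = sample(0:50, 1e4, TRUE))
  counts <- counts[2 * counts$tp + counts$fp + counts$fn > 0, ]
  d <- vapply(seq_len(nrow(counts)), function(i) dsc(counts[i, ]), 0)
  j <- vapply(seq_len(nrow(counts)), function(i) iou(counts[i, ]), 0)
  expect_lt(max(abs(j - d / (2 - d))), 1e-12)
  expect_true(all(d >= j & d >= 0 & d <= 1 & j >= 0))
})

test_that("boundary extraction uses 4-neighbours with border-as-background", {
  full <- matrix(1L, 5, 5)
  b <- extract_boundary(full, 1)
  expect_equal(nrow(b$points), 16)                 # frame pixels only

  single <- matrix(0L, 5, 5); single[3, 4] <- 1L
  bs <- extract_boundary(single, 2)
  expect_equal(unname(bs$points), matrix(c(2, 3) * 2, 1, 2))

  sq <- matrix(0L, 5, 5); sq[2:4, 2:4] <- 1L
  expect_equal(nrow(extract_boundary(sq, 1)$points), 8)  # 3x3 solid square

  expect_error(extract_boundary(matrix(0L, 3, 3)), "empty mask")
})

test_that("singleton point sets give the textbook distances", {
  a <- matrix(c(0, 0), 1, 2)
  b <- matrix(c(3, 4), 1, 2)
  expect_equal(hd95(a, b), 5.0)      # 3-4-5 triangle
  expect_equal(assd(a, a), 0)
  expect_equal(hd95(a, a), 0)
  c2 <- matrix(c(0, 2), 1, 2)
  expect_equal(assd(a, c2), 2.0)     # (2 + 2) / 2
})

test_that("hd95 and assd agree with brute force on random mask pairs", {
  set.seed(52)
  for (i in 1:50) {
    H <- sample(4:16, 1); W <- sample(4:16, 1)
    m1 <- random_mask(H, W); m2 <- random_mask(H, W)
    if (!any(m1 == 1) || !any(m2 == 1)) next
    sp <- runif(1, 0.3, 2)
    b1 <- extract_boundary(m1, sp); b2 <- extract_boundary(m2, sp)
    p1 <- brute_boundary(m1, sp); p2 <- brute_boundary(m2, sp)
    expect_equal(nrow(b1$points), nrow(p1))
    expect_equal(hd95(b1, b2), brute_hd95(p1, p2), tolerance = 1e-10)
    expect_equal(assd(b1, b2), brute_assd(p1, p2), tolerance = 1e-10)
    # symmetry
    expect_equal(hd95(b1, b2), hd95(b2, b1))
    expect_equal(assd(b1, b2), assd(b2, b1))
    # linear scaling with pixel spacing
    b1u <- extract_boundary(m1, 1); b2u <- extract_boundary(m2, 1)
    expect_equal(hd95(b1, b2), sp * hd95(b1u, b2u), tolerance = 1e-10)
    expect_equal(assd(b1, b2), sp * assd(b1u, b2u), tolerance = 1e-10)
  }
})

test_that("directed hd95 variant bounds the pooled one from above", {
  set.seed(53)
  for (i in 1:20) {
    m1 <- random_mask(10, 10); m2 <- random_mask(10, 10)
    if (!any(m1 == 1) || !any(m2 == 1)) next
    b1 <- extract_boundary(m1); b2 <- extract_boundary(m2)
    expect_gte(hd95(b1, b2, method = "directed") + 1e-12, hd95(b1, b2))
  }
})

test_that("metric_report aggregates per class with missing boundaries as NA", {
  y <- matrix(0L, 8, 8); y[2:4, 2:4] <- 1L; y[6:7, 5:8] <- 2L
  p <- y
  r <- metric_report(p, y, spacing_mm = 0.5, n_classes = 3L)
  expect_equal(r$dsc[r$class == "1"], 1)
  expect_equal(r$hd95_mm[r$class == "2"], 0)
  expect_equal(r$dsc[r$class == "mean"], 1)

  p2 <- matrix(0L, 8, 8); p2[2:4, 2:4] <- 1L     # class 2 never predicted
  r2 <- metric_report(p2, y, spacing_mm = 0.5, n_classes = 3L)
  expect_true(is.na(r2$hd95_mm[r2$class == "2"]))
  expect_equal(r2$dsc[r2$class == "2"], 0)
})
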