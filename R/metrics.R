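# Evaluation metrics: confusion-count overlap measures (DSC, IoU) and
# physically scaled boundary-distance measures (HD95, ASSD).

#' Confusion counts for one label
#'
#' @param pred_mask,target_mask integer label masks of identical shape.
#' @param positive_label the label counted as positive (default 1).
#' @return object of class `confusion_counts`: list with `tp`, `fp`, `fn`,
#'   `tn` (summing to the pixel count).
#' @export
confusion_counts <- function(pred_mask, target_mask, positive_label = 1L) {
  if (!identical(dim_of(pred_mask), dim_of(target_mask))) {
    stop("shape error: prediction and target differ in shape")
  }
  p <- pred_mask == positive_label
  y <- target_mask == positive_label
  structure(list(tp = sum(p & y), fp = sum(p & !y),
                 fn = sum(!p & y), tn = sum(!p & !y)),
            class = "confusion_counts")
}

#' Dice similarity coefficient from confusion counts
#'
#' `2 TP / (2 TP + FN + FP)`; an all-empty pair (no positives anywhere in
#' prediction or target) scores 1 by the perfect-absence convention.
#'
#' @param c a [confusion_counts()] object (or compatible list).
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(c) {
  den <- 2 * c$tp + c$fn + c$fp
  if (den == 0) return(1)
  2 * c$tp / den
}

#' Intersection over union (Jaccard index) from confusion counts
#'
#' `TP / (TP + FN + FP)`; satisfies `iou = dsc / (2 - dsc)` exactly.
#'
#' @inheritParams dsc
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(c) {
  den <- c$tp + c$fn + c$fp
  if (den == 0) return(1)
  c$tp / den
}

#' Extract the boundary point set of a binary mask
#'
#' Boundary pixels are foreground pixels with at least one background
#' 4-neighbour, where the image border counts as background. Pixel centres
#' are scaled by the physical pixel spacing; pixel `(i, j)` (1-based) maps to
#' `((i - 1) * spacing, (j - 1) * spacing)` mm.
#'
#' @param mask binary (logical or 0/1 integer) matrix.
#' @param spacing_mm physical pixel spacing in mm.
#' @return object of class `boundary_points`: list with `points` (n x 2
#'   matrix of mm coordinates) and `spacing_mm`.
#' @export
extract_boundary <- function(mask, spacing_mm = 1) {
  m <- mask != 0
  if (!any(m)) stop("empty mask: no foreground pixels, boundary undefined")
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  core <- pad[2:(H + 1L), 2:(W + 1L)]
  nb <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
        pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  boundary <- core & !nb
  idx <- which(boundary, arr.ind = TRUE)
  structure(list(points = (idx - 1) * spacing_mm, spacing_mm = spacing_mm),
            class = "boundary_points")
}

cross_min_dists <- function(a, b) {
  # for each row of a, distance to the nearest row of b (exact coordinate
  # differences; the expanded quadratic form loses precision)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(do.call(pmin, as.data.frame(d2)))
}

as_points <- function(b) {
  if (inherits(b, "boundary_points")) b$points else as.matrix(b)
}

check_nonempty <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("undefined metric: empty boundary point set")
  }
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' Robust boundary distance: the 95th percentile (linear interpolation
#' between order statistics) of the nearest-neighbour distances between two
#' boundary point sets. The default pools both directed distance multisets
#' before taking the percentile, matching common medical-segmentation
#' tooling; `method = "directed"` instead takes the maximum of the two
#' directed 95th percentiles.
#'
#' @param b1,b2 [extract_boundary()] results or n x 2 coordinate matrices
#'   in mm.
#' @param method `"pooled"` (default) or `"directed"`.
#' @return HD95 in mm; symmetric, nonnegative, zero iff the sets coincide.
#' @export
hd95 <- function(b1, b2, method = c("pooled", "directed")) {
  method <- match.arg(method)
  a <- as_points(b1); b <- as_points(b2)
  check_nonempty(a, b)
  d_ab <- cross_min_dists(a, b)
  d_ba <- cross_min_dists(b, a)
  if (method == "pooled") {
    unname(stats::quantile(c(d_ab, d_ba), 0.95, type = 7))
  } else {
    max(stats::quantile(d_ab, 0.95, type = 7),
        stats::quantile(d_ba, 0.95, type = 7))
  }
}

#' Average symmetric surface distance (mm)
#'
#' The sum over each set of nearest-neighbour distances to the other set,
#' divided by the total number of boundary points.
#'
#' @inheritParams hd95
#' @return ASSD in mm; symmetric, nonnegative, zero iff the sets coincide.
#' @export
assd <- function(b1, b2) {
  a <- as_points(b1); b <- as_points(b2)
  check_nonempty(a, b)
  (sum(cross_min_dists(a, b)) + sum(cross_min_dists(b, a))) /
    (nrow(a) + nrow(b))
}

#' Full metric report for a prediction / ground-truth pair
#'
#' Computes DSC, IoU, HD95 and ASSD for each non-background class, plus
#' their mean for multiclass masks. Boundary metrics are `NA` when either
#' boundary set is empty (reported as missing, never 0).
#'
#' @param pred_mask,target_mask integer label masks.
#' @param spacing_mm physical pixel spacing in mm.
#' @param n_classes number of classes (default: inferred from the masks).
#' @return a `metric_report` data.frame with columns `class`, `dsc`, `iou`,
#'   `hd95_mm`, `assd_mm`; the last row (`class = "mean"`) averages over
#'   classes for multiclass masks.
#' @export
metric_report <- function(pred_mask, target_mask, spacing_mm = 1,
                          n_classes = NULL) {
  if (is.null(n_classes)) {
    n_classes <- max(2L, max(pred_mask, target_mask) + 1L)
  }
  rows <- lapply(seq_len(n_classes - 1L), function(k) {
    cc <- confusion_counts(pred_mask, target_mask, k)
    h <- a <- NA_real_
    if (any(pred_mask == k) && any(target_mask == k)) {
      bp <- extract_boundary(pred_mask == k, spacing_mm)
      bt <- extract_boundary(target_mask == k, spacing_mm)
      h <- hd95(bp, bt)
      a <- assd(bp, bt)
    }
    data.frame(class = as.character(k), dsc = dsc(cc), iou = iou(cc),
               hd95_mm = h, assd_mm = a)
  })
  out <- do.call(rbind, rows)
  if (n_classes > 2L) {
    out <- rbind(out, data.frame(class = "mean", dsc = mean(out$dsc),
                                 iou = mean(out$iou),
                                 hd95_mm = mean(out$hd95_mm),
                                 assd_mm = mean(out$assd_mm)))
  }
  class(out) <- c("metric_report", "data.frame")
  out
}
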