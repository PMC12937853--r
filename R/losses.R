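# Hybrid segmentation loss: soft Dice + focal cross-entropy, combined as
# alpha * Dice + beta * Focal, with inverse-frequency class weights.

#' Loss configuration
#'
#' @param alpha weight of the Dice term.
#' @param beta weight of the focal term.
#' @param gamma focusing parameter of the focal term (default 2): the
#'   per-pixel focal contribution is scaled by `(1 - P)^gamma`, suppressing
#'   well-classified pixels.
#' @param class_weights positive per-class weights `alpha_k` (length = number
#'   of classes); `NULL` means uniform.
#' @param epsilon smoothing constant inside the focal logarithm
#'   (default 1e-5), keeping the loss finite at `P = 0`.
#' @return a `loss_config` list.
#' @export
loss_config <- function(alpha = 0.5, beta = 0.5, gamma = 2,
                        class_weights = NULL, epsilon = 1e-5) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be nonnegative")
  if (alpha + beta <= 0) stop("alpha + beta must be positive")
  if (gamma < 0) stop("gamma must be nonnegative")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (!is.null(class_weights) && any(class_weights <= 0)) {
    stop("class weights must be positive")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 class_weights = class_weights, epsilon = epsilon),
            class = "loss_config")
}

dice_binary <- function(p, y) {
  sp <- sum(p); sy <- sum(y)
  if (sp + sy == 0) return(0)          # perfect-absence convention
  1 - 2 * sum(p * y) / (sp + sy)
}

#' Soft Dice loss
#'
#' `1 - 2 sum(p y) / (sum(p) + sum(y))` over the foreground for a binary
#' prediction, or the average of the per-class soft Dice over all
#' non-background classes for a multiclass prediction. When target and
#' prediction are both empty the class contributes 0 (perfect absence).
#'
#' @param pred_prob predicted probabilities: matrix `(H, W)` of foreground
#'   probability, or array `(H, W, K)` of per-class probabilities with
#'   class 1 the background.
#' @param target_mask integer label mask `(H, W)` (0 = background).
#' @return Dice loss in `[0, 1]`.
#' @export
dice_loss <- function(pred_prob, target_mask) {
  if (min(pred_prob) < 0 || max(pred_prob) > 1) {
    stop("value error: probabilities must lie in [0, 1]")
  }
  d <- dim_of(pred_prob)
  if (length(d) == 2L || (length(d) == 3L && d[3] == 1L)) {
    return(dice_binary(as.numeric(pred_prob), as.numeric(target_mask == 1)))
  }
  K <- d[3]
  vals <- vapply(seq_len(K - 1L), function(k) {
    dice_binary(as.numeric(pred_prob[, , k + 1L]),
                as.numeric(target_mask == k))
  }, 0)
  mean(vals)
}

#' Focal loss
#'
#' One-hot focal cross-entropy: the mean over pixels of
#' `-alpha_k (1 - P)^gamma log(P + epsilon)` where `P` is the predicted
#' probability of each pixel's true class. Finite for all inputs thanks to
#' `epsilon`.
#'
#' @param pred_prob array `(H, W, K)` of per-class probabilities summing to
#'   one over classes, or matrix `(H, W)` of foreground probability for the
#'   binary task.
#' @param target_mask integer label mask `(H, W)`.
#' @param cfg a [loss_config()].
#' @return nonnegative focal loss.
#' @export
focal_loss <- function(pred_prob, target_mask, cfg = loss_config()) {
  if (min(pred_prob) < 0 || max(pred_prob) > 1) {
    stop("value error: probabilities must lie in [0, 1]")
  }
  d <- dim_of(pred_prob)
  if (length(d) == 2L || (length(d) == 3L && d[3] == 1L)) {
    p <- as.numeric(pred_prob)
    pred_prob <- array(c(1 - p, p), dim = c(d[1], d[2], 2L))
    d <- dim(pred_prob)
  }
  K <- d[3]
  w <- cfg$class_weights %||% rep(1, K)
  if (length(w) != K) stop("class_weights must have length ", K)
  lab <- as.integer(target_mask) + 1L             # 1-based class index
  pm <- matrix(pred_prob, ncol = K)
  ptrue <- pm[cbind(seq_along(lab), lab)]
  mean(-w[lab] * (1 - ptrue)^cfg$gamma * log(ptrue + cfg$epsilon))
}

#' Hybrid Dice + focal loss
#'
#' Activates logits (sigmoid for a single-channel binary map, softmax across
#' channels otherwise) and returns `alpha * Dice + beta * Focal` together
#' with both components; exactly bilinear in `(alpha, beta)`.
#'
#' @param pred_logits raw network outputs: matrix `(H, W)` (binary) or array
#'   `(H, W, K)`.
#' @param target_mask integer label mask `(H, W)`.
#' @param cfg a [loss_config()].
#' @return list with `total`, `dice`, `focal`.
#' @export
hybrid_loss <- function(pred_logits, target_mask, cfg = loss_config()) {
  d <- dim_of(pred_logits)
  if (length(d) == 2L || (length(d) == 3L && d[3] == 1L)) {
    p <- 1 / (1 + exp(-as.numeric(pred_logits)))
    prob2 <- array(c(1 - p, p), dim = c(d[1], d[2], 2L))
    dice <- dice_loss(matrix(p, d[1], d[2]), target_mask)
    focal <- focal_loss(prob2, target_mask, cfg)
  } else {
    prob <- ag_no_grad(ag_softmax_c(ag_const(to4(pred_logits))))$value
    prob <- from4(prob, 3L)
    dice <- dice_loss(prob, target_mask)
    focal <- focal_loss(prob, target_mask, cfg)
  }
  list(total = cfg$alpha * dice + cfg$beta * focal, dice = dice, focal = focal)
}

#' Inverse-frequency class weights
#'
#' Computes per-class balancing weights proportional to the inverse label
#' frequency over a collection of masks, normalized to mean one. Classes
#' absent from every mask receive the maximum observed weight, so a rarer
#' class always gets a strictly larger weight than a commoner one.
#'
#' @param masks a label mask or list of label masks.
#' @param K number of classes.
#' @return numeric vector of `K` positive weights with mean 1.
#' @export
class_weights_from_frequencies <- function(masks, K) {
  if (!is.list(masks)) masks <- list(masks)
  if (length(masks) == 0L) stop("value error: no masks given")
  counts <- numeric(K)
  for (m in masks) counts <- counts + tabulate(as.integer(m) + 1L, nbins = K)
  total <- sum(counts)
  if (total == 0) stop("value error: masks contain no pixels")
  freq <- counts / total
  w <- ifelse(counts > 0, 1 / freq, NA_real_)
  w[is.na(w)] <- max(w, na.rm = TRUE)
  w / mean(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- autograd versions used by the training loop ---------------------------

# prob: (H,W,K,N) softmax probabilities; target: (H,W,N) integer labels.
ag_dice_loss <- function(prob, target, K) {
  terms <- list()
  for (k in seq_len(K - 1L)) {
    pk <- ag_slice_c(prob, k + 1L)
    y <- array(as.numeric(target == k), dim = dim(pk$value))
    sy <- sum(y)
    if (sy == 0 && sum(pk$value) == 0) {       # perfect absence
      terms[[length(terms) + 1L]] <- ag_const(0)
      next
    }
    num <- ag_scale(ag_sum(ag_mul(pk, y)), 2)
    den <- ag_add(ag_sum(pk), sy)
    terms[[length(terms) + 1L]] <- ag_sub(1, ag_div(num, den))
  }
  if (length(terms) == 0L) return(ag_const(0))
  acc <- terms[[1]]
  if (length(terms) > 1L) for (i in 2:length(terms)) acc <- ag_add(acc, terms[[i]])
  ag_scale(acc, 1 / length(terms))
}

ag_focal_loss <- function(prob, target, cfg, K) {
  d <- dim(prob$value)
  onehot <- array(0, dim = d)
  wmap <- array(0, dim = c(d[1], d[2], 1, d[4]))
  w <- cfg$class_weights %||% rep(1, K)
  for (k in seq_len(K)) {
    sel <- target == (k - 1L)
    onehot[, , k, ][sel] <- 1
    wmap[, , 1, ][sel] <- w[k]
  }
  ptrue <- ag_sum_c(ag_mul(prob, onehot))
  term <- ag_mul(ag_pow(ag_sub(1, ptrue), cfg$gamma),
                 ag_log_shift(ptrue, cfg$epsilon))
  ag_scale(ag_sum(ag_mul(term, wmap)), -1 / (d[1] * d[2] * d[4]))
}

ag_hybrid_loss <- function(logits, target, cfg, K) {
  prob <- ag_softmax_c(logits)
  dice <- ag_dice_loss(prob, target, K)
  focal <- ag_focal_loss(prob, target, cfg, K)
  total <- ag_add(ag_scale(dice, cfg$alpha), ag_scale(focal, cfg$beta))
  list(total = total, dice = dice, focal = focal)
}
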