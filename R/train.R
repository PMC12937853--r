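# Training, cross-validation, and inference orchestration: AdamW on the
# hybrid Dice+focal loss with deep-supervision auxiliaries, cosine-annealed
# learning rate, and early stopping on validation DSC.

#' Training configuration
#'
#' @param network a [network_config()].
#' @param loss a [loss_config()].
#' @param augmentation an [augment_config()].
#' @param lr_initial,lr_min initial / minimum learning rate of the cosine
#'   schedule (defaults 1e-4 and 1e-6).
#' @param cosine_period_epochs cosine cycle length in epochs (default 1000);
#'   training beyond one period restarts the cycle (warm restart).
#' @param weight_decay decoupled AdamW weight decay (default 1e-4).
#' @param early_stop_patience_epochs stop after this many consecutive
#'   epochs without a validation-DSC increase (default 20).
#' @param batch_size,max_epochs batch size and epoch budget.
#' @param seed RNG seed covering weight init, shuffling and augmentation.
#' @param aux_weights deep-supervision loss weights, deepest stage first.
#' @param target_val_dsc optional convenience stop: end training once the
#'   validation DSC exceeds this value (`NULL` to disable).
#' @return a `train_config` list.
#' @export
train_config <- function(network = network_config(),
                         loss = loss_config(),
                         augmentation = augment_config(),
                         lr_initial = 1e-4, lr_min = 1e-6,
                         cosine_period_epochs = 1000L,
                         weight_decay = 1e-4,
                         early_stop_patience_epochs = 20L,
                         batch_size = 8L, max_epochs = 100L,
                         seed = 1L,
                         aux_weights = c(0.4, 0.3, 0.2, 0.1),
                         target_val_dsc = NULL) {
  if (lr_min >= lr_initial) stop("lr_min must be < lr_initial")
  if (early_stop_patience_epochs < 1L) stop("patience must be >= 1")
  if (batch_size < 1L || max_epochs < 1L) stop("batch_size and max_epochs must be >= 1")
  structure(list(network = network, loss = loss, augmentation = augmentation,
                 lr_initial = lr_initial, lr_min = lr_min,
                 cosine_period_epochs = as.integer(cosine_period_epochs),
                 weight_decay = weight_decay,
                 early_stop_patience_epochs = as.integer(early_stop_patience_epochs),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), aux_weights = aux_weights,
                 target_val_dsc = target_val_dsc),
            class = "train_config")
}

#' Cosine-annealed learning rate at an epoch
#'
#' `lr_min + 0.5 (lr_initial - lr_min) (1 + cos(pi (epoch mod period) / period))`.
#'
#' @param epoch epoch index (0-based).
#' @param cfg a [train_config()].
#' @return the learning rate.
#' @export
lr_at <- function(epoch, cfg) {
  p <- cfg$cosine_period_epochs
  cfg$lr_min + 0.5 * (cfg$lr_initial - cfg$lr_min) *
    (1 + cos(pi * (epoch %% p) / p))
}

stack_batch <- function(samples) {
  H <- nrow(samples[[1]]$image); W <- ncol(samples[[1]]$image)
  N <- length(samples)
  x <- array(0, dim = c(H, W, 1L, N))
  y <- array(0L, dim = c(H, W, N))
  for (i in seq_len(N)) {
    x[, , 1, i] <- samples[[i]]$image
    y[, , i] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}

# mean foreground DSC over samples (binary) or mean over non-background
# classes (multiclass), from argmax masks.
batch_dsc <- function(logits, target, n_classes) {
  N <- dim(logits)[4]
  vals <- numeric(N)
  for (i in seq_len(N)) {
    pred <- apply(logits[, , , i, drop = FALSE][, , , 1], c(1, 2), which.max) - 1L
    per_class <- vapply(seq_len(n_classes - 1L), function(k) {
      dsc(confusion_counts(pred, target[, , i], k))
    }, 0)
    vals[i] <- mean(per_class)
  }
  mean(vals)
}

eval_dsc <- function(net, samples) {
  b <- stack_batch(samples)
  out <- wmca_forward(net, b$x, train = FALSE)
  batch_dsc(out$logits, b$y, net$config$n_classes)
}

aux_loss_ag <- function(aux, target, weights) {
  total <- NULL
  fg <- (target > 0) * 1
  H <- dim(target)[1]; W <- dim(target)[2]; N <- dim(target)[3]
  for (i in seq_along(aux)) {
    a <- aux[[i]]
    if (is.null(a)) next
    d <- dim(a$value)
    # area-averaged soft foreground target at the head's resolution: a
    # nearest-neighbour target can miss thin structures entirely at the
    # deepest stages, starving the head of gradient
    if (H %% d[1] == 0L && W %% d[2] == 0L) {
      fh <- H %/% d[1]; fw <- W %/% d[2]
      v <- array(fg, dim = c(fh, d[1], fw, d[2], N))
      s1 <- aperm(colSums(v, dims = 1), c(2, 1, 3, 4))
      yt <- array(colSums(s1, dims = 1) / (fh * fw), dim = c(d[1], d[2], 1, d[4]))
    } else {
      ri <- round(seq(1, H, length.out = d[1]))
      ci <- round(seq(1, W, length.out = d[2]))
      yt <- array(fg[ri, ci, , drop = FALSE], dim = c(d[1], d[2], 1, d[4]))
    }
    sy <- sum(yt)
    term <- if (sy == 0 && sum(a$value) == 0) ag_const(0) else {
      ag_sub(1, ag_div(ag_scale(ag_sum(ag_mul(a, yt)), 2),
                       ag_add(ag_sum(a), sy)))
    }
    total <- if (is.null(total)) ag_scale(term, weights[i]) else {
      ag_add(total, ag_scale(term, weights[i]))
    }
  }
  total
}

#' Train a WMCA-Net
#'
#' Optimizes the hybrid Dice+focal loss (plus weighted deep-supervision
#' auxiliary Dice terms) with AdamW under the cosine learning-rate
#' schedule, logging per-epoch training loss and validation DSC, stopping
#' early when validation DSC has not increased for the configured patience,
#' and returning the parameters of the best validation epoch.
#'
#' @param cfg a [train_config()].
#' @param train_samples,val_samples lists of `image_sample`s (non-empty).
#' @param out_dir optional directory for the run record CSV, the resolved
#'   config YAML and the best checkpoint.
#' @param verbose print per-epoch progress.
#' @return list with `record` (per-epoch data.frame), `net` (best weights),
#'   `best_epoch`, `best_val_dsc`, `checkpoint_path` (when `out_dir` given).
#' @export
train <- function(cfg, train_samples, val_samples, out_dir = NULL,
                  verbose = FALSE) {
  if (length(train_samples) == 0L || length(val_samples) == 0L) {
    stop("configuration error: training and validation splits must be non-empty")
  }
  set.seed(cfg$seed)
  net <- build_network(cfg$network)
  params <- collect_params(net)
  opt <- adamw_state(params)
  K <- cfg$network$n_classes

  best_dsc <- -Inf
  best_params <- param_values(net)
  best_epoch <- 0L
  since_best <- 0L
  record <- list()

  for (epoch in seq_len(cfg$max_epochs) - 1L) {
    lr <- lr_at(epoch, cfg)
    idx <- sample(length(train_samples))
    ep_loss <- ep_dice <- ep_focal <- 0
    nb <- 0L
    for (start in seq(1, length(idx), by = cfg$batch_size)) {
      take <- idx[start:min(start + cfg$batch_size - 1L, length(idx))]
      samples <- lapply(train_samples[take], augment, cfg = cfg$augmentation)
      b <- stack_batch(samples)
      zero_grads(params)
      out <- wmca_forward_ag(net, ag_const(b$x), train = TRUE)
      loss <- ag_hybrid_loss(out$logits, b$y, cfg$loss, K)
      total <- loss$total
      if (length(out$aux) > 0) {
        at <- aux_loss_ag(out$aux, b$y, cfg$aux_weights)
        if (!is.null(at)) total <- ag_add(total, at)
      }
      ag_backward(total)
      opt <- adamw_step(params, opt, lr, cfg$weight_decay)
      ep_loss <- ep_loss + as.numeric(total$value)
      ep_dice <- ep_dice + as.numeric(loss$dice$value)
      ep_focal <- ep_focal + as.numeric(loss$focal$value)
      nb <- nb + 1L
    }
    val_dsc <- eval_dsc(net, val_samples)
    record[[length(record) + 1L]] <- data.frame(
      epoch = epoch, lr = lr, loss_total = ep_loss / nb,
      loss_dice = ep_dice / nb, loss_focal = ep_focal / nb,
      val_dsc = val_dsc)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val DSC %.4f",
                      epoch, lr, ep_loss / nb, val_dsc))
    }
    if (val_dsc > best_dsc) {
      best_dsc <- val_dsc
      best_params <- param_values(net)
      best_epoch <- epoch
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$early_stop_patience_epochs) break
    }
    if (!is.null(cfg$target_val_dsc) && best_dsc > cfg$target_val_dsc) break
  }

  set_param_values(net, best_params)
  result <- list(record = do.call(rbind, record), net = net,
                 best_epoch = best_epoch, best_val_dsc = best_dsc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(result$record, file.path(out_dir, "run_record.csv"),
                     row.names = FALSE)
    write_run_config(cfg, file.path(out_dir, "resolved_config.yaml"))
    result$checkpoint_path <- file.path(out_dir, "best_checkpoint.rds")
    save_checkpoint(net, result$checkpoint_path)
  }
  result
}

#' K-fold cross-validation
#'
#' Deterministic seeded fold assignment (every sample in exactly one
#' validation fold), one training run per fold, and per-fold plus mean/sd
#' foreground metrics.
#'
#' @param cfg a [train_config()].
#' @param samples list of `image_sample`s (length >= k).
#' @param k number of folds (default 5).
#' @return list with `folds` (assignment vector), `per_fold` (data.frame of
#'   per-fold mean metrics), `mean` and `sd` rows.
#' @export
crossval <- function(cfg, samples, k = 5L) {
  n <- length(samples)
  if (k > n) stop("configuration error: k exceeds the dataset size")
  folds <- local_seed(cfg$seed, sample(rep(seq_len(k), length.out = n)))
  per_fold <- list()
  for (f in seq_len(k)) {
    fit <- train(cfg, samples[folds != f], samples[folds == f])
    reports <- lapply(samples[folds == f], function(s) {
      pred <- predict_mask(fit$net, s$image)
      metric_report(pred, s$mask, s$pixel_spacing_mm, cfg$network$n_classes)
    })
    agg <- do.call(rbind, lapply(reports, function(r) r[nrow(r), -1]))
    per_fold[[f]] <- data.frame(fold = f, t(colMeans(agg, na.rm = TRUE)))
  }
  per_fold <- do.call(rbind, per_fold)
  list(folds = folds, per_fold = per_fold,
       mean = colMeans(per_fold[-1]),
       sd = apply(per_fold[-1], 2, stats::sd))
}

#' Predict a label mask for one image
#'
#' Eval-mode forward pass plus channel argmax. Inputs whose spatial size is
#' not divisible by 16 are reflect-padded, predicted, and cropped back.
#'
#' @param net a trained `wmca_net`.
#' @param image grayscale matrix in `[0, 1]`.
#' @return integer label mask of the input's shape.
#' @export
predict_mask <- function(net, image) {
  H <- nrow(image); W <- ncol(image)
  Hp <- 16L * ((H + 15L) %/% 16L)
  Wp <- 16L * ((W + 15L) %/% 16L)
  padded <- image[c(seq_len(H), rev(seq_len(Hp - H) + H - (Hp - H))),
                  c(seq_len(W), rev(seq_len(Wp - W) + W - (Wp - W))),
                  drop = FALSE]
  out <- wmca_forward(net, padded)
  pred <- apply(out$logits[, , , 1], c(1, 2), which.max) - 1L
  pred[seq_len(H), seq_len(W), drop = FALSE]
}

#' Batch prediction to files
#'
#' Writes argmax masks (`<stem>_pred.png`, labels stored losslessly) and
#' optional red/green overlay PNGs (ground truth green, prediction red) for
#' each input sample.
#'
#' @param net a trained `wmca_net` or a checkpoint path.
#' @param samples list of `image_sample`s.
#' @param out_dir output directory.
#' @param overlay also write RGB overlay images.
#' @return character vector of written mask paths.
#' @export
predict_masks <- function(net, samples, out_dir, overlay = FALSE) {
  if (is.character(net)) net <- load_checkpoint(net)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    pred <- predict_mask(net, s$image)
    stem <- file.path(out_dir, sprintf("sample_%04d", i))
    paths[i] <- paste0(stem, "_pred.png")
    png::writePNG(pred / 255, paths[i])
    if (overlay) {
      rgb <- array(s$image, dim = c(nrow(pred), ncol(pred), 3))
      rgb[, , 1][pred > 0] <- 1
      rgb[, , 2][s$mask > 0] <- 1
      png::writePNG(pmin(pmax(rgb, 0), 1), paste0(stem, "_overlay.png"))
    }
  }
  invisible(paths)
}

#' Evaluate predicted masks against ground truth
#'
#' Pairs `<stem>_pred.png` files with `<stem>_msk.png` ground truth files,
#' computes the metric suite per sample and class, and writes a CSV with
#' columns `sample_id`, `class`, `dsc`, `iou`, `hd95_mm`, `assd_mm`.
#'
#' @param pred_dir,gt_dir directories of predictions and ground truth.
#' @param spacing_mm physical pixel spacing.
#' @param out_csv output CSV path (optional).
#' @return the per-sample data.frame.
#' @export
evaluate_masks <- function(pred_dir, gt_dir, spacing_mm = 0.5,
                           out_csv = NULL) {
  preds <- sort(list.files(pred_dir, pattern = "_pred\\.png$", full.names = TRUE))
  if (length(preds) == 0L) stop("no prediction files found in ", pred_dir)
  rows <- list()
  for (p in preds) {
    stem <- sub("_pred\\.png$", "", basename(p))
    gt_path <- file.path(gt_dir, paste0(stem, "_msk.png"))
    if (!file.exists(gt_path)) stop("missing ground truth for ", stem)
    pred <- read_mask_png(p)
    gt <- read_mask_png(gt_path)
    rep <- metric_report(pred, gt, spacing_mm)
    rep <- cbind(sample_id = stem, rep)
    rows[[length(rows) + 1L]] <- rep
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
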