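# Patch-based 3D U-Net segmentation with the full training protocol: SGD
# (momentum + Nesterov + 1/(1+decay*t) rate decay), whole-volume
# validation Dice after every epoch, early stopping on a patience window,
# replicate training and median-network selection.

#' Training configuration
#'
#' Defaults are the full-scale protocol: 64^3 patches scaled to 256^3
#' volumes, stride 32, batch size 24, SGD with learning rate 0.01, decay
#' 1e-6, momentum 0.9 and Nesterov enabled, early stopping with a
#' 25-epoch patience inside a 200-epoch cap, and three replicate
#' networks. [desk_config()] gives a configuration that trains in
#' minutes on a laptop CPU.
#'
#' @param patch_size_vox Integer triple, sliding-window patch size.
#' @param target_scale_vox Integer triple or `NULL`; volumes are
#'   resampled to this size (trilinear for grey, nearest for labels)
#'   before patch extraction, and predictions are resampled back.
#' @param stride_vox Integer stride of the patch grid.
#' @param batch_size Patches per gradient step.
#' @param learning_rate,decay,momentum,nesterov SGD hyperparameters.
#' @param patience_epochs Early stopping: training ends when validation
#'   Dice has not improved within this many epochs.
#' @param max_epochs Epoch cap.
#' @param n_replicates Replicate networks per training set.
#' @param base_channels Channel width of the first U-Net level (widths
#'   double per level).
#' @param crop_to_foreground Crop training volumes to the foreground
#'   bounding box (padded to patch size) before patch extraction.
#' @param class_weights `NULL` (default, unweighted cross-entropy) or a
#'   numeric vector of three positive per-class loss weights
#'   (background, external, internal). Up-weighting the rare foreground
#'   classes helps narrow desk-scale networks learn the internal cavity.
#' @param seed Integer seed governing weight init and patch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(patch_size_vox = c(64L, 64L, 64L),
                         target_scale_vox = c(256L, 256L, 256L),
                         stride_vox = 32L,
                         batch_size = 24L,
                         learning_rate = 0.01,
                         decay = 1e-6,
                         momentum = 0.9,
                         nesterov = TRUE,
                         patience_epochs = 25L,
                         max_epochs = 200L,
                         n_replicates = 3L,
                         base_channels = 8L,
                         crop_to_foreground = FALSE,
                         class_weights = NULL,
                         seed = 1L) {
  if (length(patch_size_vox) == 1L) patch_size_vox <- rep(patch_size_vox, 3L)
  cfg <- list(patch_size_vox = as.integer(patch_size_vox),
              target_scale_vox = if (is.null(target_scale_vox)) NULL
                else as.integer(rep(target_scale_vox,
                                    length.out = 3L)),
              stride_vox = as.integer(stride_vox),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate, decay = decay,
              momentum = momentum, nesterov = isTRUE(nesterov),
              patience_epochs = as.integer(patience_epochs),
              max_epochs = as.integer(max_epochs),
              n_replicates = as.integer(n_replicates),
              base_channels = as.integer(base_channels),
              crop_to_foreground = isTRUE(crop_to_foreground),
              class_weights = class_weights,
              seed = as.integer(seed))
  if (!is.null(cfg$class_weights))
    stopifnot(length(cfg$class_weights) == 3L,
              all(cfg$class_weights > 0))
  stopifnot(all(cfg$patch_size_vox >= 4L),
            all(cfg$patch_size_vox %% 4L == 0L),
            cfg$stride_vox >= 1L,
            cfg$stride_vox <= min(cfg$patch_size_vox),
            cfg$batch_size >= 1L, cfg$learning_rate > 0, cfg$decay >= 0,
            cfg$momentum >= 0, cfg$momentum < 1,
            cfg$patience_epochs >= 1L,
            cfg$patience_epochs <= cfg$max_epochs,
            cfg$n_replicates >= 1L, cfg$base_channels >= 1L)
  class(cfg) <- "train_config"
  cfg
}

#' Desk-scale training configuration
#'
#' The full-scale hyperparameters applied at a scale that trains on a CPU
#' in minutes: volumes resampled to 64^3, 16^3 patches, stride 8, batch
#' 8, a narrow U-Net. All SGD settings, patience and the epoch cap keep
#' their full-scale values unless overridden.
#'
#' @param ... Overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
desk_config <- function(...) {
  args <- list(patch_size_vox = c(16L, 16L, 16L),
               target_scale_vox = c(64L, 64L, 64L),
               stride_vox = 8L, batch_size = 8L, base_channels = 4L)
  override <- list(...)
  args[names(override)] <- override
  do.call(train_config, args)
}

.patch_origins <- function(len, patch, stride) {
  if (len < patch)
    stop(sprintf("volume extent %d smaller than patch extent %d", len,
                 patch))
  o <- seq.int(0L, len - patch, by = stride)
  if (o[length(o)] + patch < len) o <- c(o, len - patch)  # boundary snap
  o
}

.foreground_bbox <- function(labels, patch) {
  fg <- which(labels != LABEL_BACKGROUND, arr.ind = TRUE)
  d <- dim(labels)
  if (nrow(fg) == 0L) return(cbind(lo = c(1L, 1L, 1L), hi = d))
  lo <- apply(fg, 2L, min)
  hi <- apply(fg, 2L, max)
  for (a in 1:3) {  # pad the box to at least one patch, clamped in-volume
    need <- patch[a] - (hi[a] - lo[a] + 1L)
    if (need > 0L) {
      lo[a] <- max(1L, lo[a] - ceiling(need / 2))
      hi[a] <- min(d[a], lo[a] + patch[a] - 1L)
      lo[a] <- max(1L, hi[a] - patch[a] + 1L)
    }
  }
  cbind(lo = lo, hi = hi)
}

# Crop/rescale one pair per the config; grey is normalized to [0, 1].
.prepare_volume <- function(pair, cfg, use_labels = TRUE) {
  grey <- pair$grey
  labels <- if (use_labels) pair$labels else NULL
  if (cfg$crop_to_foreground && use_labels) {
    bb <- .foreground_bbox(labels, cfg$patch_size_vox)
    grey <- grey[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2],
                 drop = FALSE]
    labels <- labels[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2],
                     bb[3, 1]:bb[3, 2], drop = FALSE]
  }
  g <- as.numeric(grey) / 65535
  d <- dim(grey)
  if (!is.null(cfg$target_scale_vox) &&
      !identical(as.integer(d), cfg$target_scale_vox)) {
    g <- resize_trilinear_cpp(g, as.integer(d), cfg$target_scale_vox)
    if (use_labels)
      labels <- array(resize_nearest_cpp(as.integer(labels), as.integer(d),
                                         cfg$target_scale_vox),
                      dim = cfg$target_scale_vox)
    d <- cfg$target_scale_vox
  }
  list(grey = array(g, dim = d), labels = labels, dim = as.integer(d))
}

#' Extract sliding-window training patches from one volume pair
#'
#' The volume is optionally foreground-cropped and rescaled per the
#' config, then covered by a patch grid at the configured stride with
#' the final window per axis snapped to the boundary, so every voxel is
#' inside at least one patch.
#'
#' @param pair A [volume_pair()].
#' @param cfg A [train_config()].
#' @return List of `list(grey, labels)` patches; `grey` is normalized to
#'   `[0, 1]`.
#' @export
extract_patches <- function(pair, cfg) {
  prep <- .prepare_volume(pair, cfg)
  p <- cfg$patch_size_vox
  og <- lapply(1:3, function(a)
    .patch_origins(prep$dim[a], p[a], cfg$stride_vox))
  out <- list()
  for (oz in og[[1]]) for (oy in og[[2]]) for (ox in og[[3]]) {
    out[[length(out) + 1L]] <- list(
      grey = prep$grey[(oz + 1):(oz + p[1]), (oy + 1):(oy + p[2]),
                       (ox + 1):(ox + p[3]), drop = FALSE],
      labels = prep$labels[(oz + 1):(oz + p[1]), (oy + 1):(oy + p[2]),
                           (ox + 1):(ox + p[3]), drop = FALSE])
  }
  out
}

.init_weights <- function(C, seed) {
  ic <- c(1L, C, C, 2L * C, 2L * C, 4L * C, 6L * C, 2L * C, 3L * C, C, C)
  oc <- c(C, C, 2L * C, 2L * C, 4L * C, 4L * C, 2L * C, 2L * C, C, C, 3L)
  .with_seed(seed, {
    w <- vector("list", 22L)
    for (l in seq_len(11L)) {
      k <- if (l == 11L) 1L else 27L
      fan_in <- ic[l] * k
      w[[2L * l - 1L]] <- rnorm(oc[l] * ic[l] * k) * sqrt(2 / fan_in)
      w[[2L * l]] <- numeric(oc[l])
    }
    w
  })
}

.copy_weights <- function(w) lapply(w, function(x) x + 0)

.predict_labels <- function(weights, C, grey_raw, cfg) {
  d <- dim(grey_raw)
  g <- as.numeric(grey_raw) / 65535
  work_dim <- as.integer(d)
  if (!is.null(cfg$target_scale_vox) &&
      !identical(work_dim, cfg$target_scale_vox)) {
    g <- resize_trilinear_cpp(g, work_dim, cfg$target_scale_vox)
    work_dim <- cfg$target_scale_vox
  }
  lab <- unet_predict_cpp(weights, g, work_dim, cfg$patch_size_vox,
                          cfg$stride_vox, C)
  if (!identical(work_dim, as.integer(d)))
    lab <- resize_nearest_cpp(lab, work_dim, as.integer(d))
  array(lab, dim = d)
}

#' Train a segmentation network on paired volumes
#'
#' Minimizes voxel-wise three-class cross-entropy by mini-batch SGD over
#' sliding-window patches pooled from all training pairs. After each
#' epoch the mean whole-volume validation Dice (foreground labels, see
#' [dice()]) is appended to the history; training stops at the epoch cap
#' or once the best epoch is `patience_epochs` behind, and the returned
#' weights are those of the best epoch. The run is deterministic given
#' `cfg$seed`.
#'
#' @param train_pairs,val_pairs Non-empty lists of [volume_pair()]s.
#' @param cfg A [train_config()].
#' @param training_set_id Identifier stored on the model.
#' @param verbose Print per-epoch progress.
#' @return Object of class `trained_model`: weights, per-epoch validation
#'   Dice `history`, `best_epoch`, `best_val_dice`, the config and the
#'   training-set id.
#' @export
train <- function(train_pairs, val_pairs, cfg, training_set_id = "train",
                  verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (!is.list(train_pairs) || length(train_pairs) == 0L)
    stop("training set is empty")
  if (!is.list(val_pairs) || length(val_pairs) == 0L)
    stop("validation set is empty")
  has_fg <- vapply(val_pairs, function(p)
    any(p$labels != LABEL_BACKGROUND), TRUE)
  if (!any(has_fg))
    stop("validation Dice undefined: no validation pair contains foreground")
  patches <- unlist(lapply(train_pairs, extract_patches, cfg = cfg),
                    recursive = FALSE)
  n_patches <- length(patches)
  pvox <- prod(cfg$patch_size_vox)
  grey_buf <- unlist(lapply(patches, function(p) as.numeric(p$grey)))
  lab_buf <- unlist(lapply(patches, function(p) as.integer(p$labels)))
  val_prep <- lapply(val_pairs, function(p) p)  # predicted at native size
  C <- cfg$base_channels
  cw <- if (is.null(cfg$class_weights)) c(1, 1, 1)
    else as.numeric(cfg$class_weights)
  .with_seed(cfg$seed, {
    weights <- .init_weights(C, seed = sample.int(2^31 - 2, 1))
    velocity <- unet_alloc_grads(C)
    history <- numeric(0)
    best <- -Inf
    best_epoch <- 0L
    best_weights <- .copy_weights(weights)
    iter <- 0
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n_patches)
      res <- unet_sgd_epoch(weights, velocity, grey_buf, lab_buf,
                            cfg$patch_size_vox, ord, cfg$batch_size, C,
                            cfg$learning_rate, cfg$momentum, cfg$decay,
                            cfg$nesterov, iter, cw)
      iter <- res$iter
      val_dice <- mean(vapply(val_prep, function(p)
        dice(.predict_labels(weights, C, p$grey, cfg), p$labels), 0))
      history <- c(history, val_dice)
      if (val_dice > best) {
        best <- val_dice
        best_epoch <- epoch
        best_weights <- .copy_weights(weights)
      }
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val Dice %.4f%s", epoch,
                        res$loss, val_dice,
                        if (epoch == best_epoch) " *" else ""))
      if (epoch - best_epoch >= cfg$patience_epochs) break
    }
    structure(list(weights = best_weights, history = history,
                   best_epoch = best_epoch, best_val_dice = best,
                   config = cfg, base_channels = C,
                   training_set_id = training_set_id),
              class = "trained_model")
  })
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<trained_model> set '%s': %d epoch(s), best val Dice %.4f at epoch %d\n",
    x$training_set_id, length(x$history), x$best_val_dice, x$best_epoch))
  invisible(x)
}

#' Predict a segmentation for a greyscale volume
#'
#' Patch-wise inference stitched over the full grid: softmax class
#' scores are accumulated over every overlapping patch and each voxel
#' takes the argmax class. Output uses the package label convention and
#' matches the input shape. Prediction is orientation-consistent only in
#' expectation, not exactly.
#'
#' @param object A `trained_model`.
#' @param grey A greyscale 3D array in the 16-bit range, or a
#'   [volume_pair()] (its `grey` channel is used).
#' @param ... Unused.
#' @return Integer label array of the same shape as the input.
#' @export
predict.trained_model <- function(object, grey, ...) {
  if (inherits(grey, "volume_pair")) grey <- grey$grey
  stopifnot(is.array(grey), length(dim(grey)) == 3L)
  .predict_labels(object$weights, object$base_channels, grey,
                  object$config)
}

#' Train replicate networks and select the median-accuracy one
#'
#' Trains `cfg$n_replicates` networks with distinct derived seeds and
#' returns all of them plus the replicate whose best validation Dice is
#' the median (for even counts, the lower middle after sorting; exact
#' ties are resolved by stable sort order).
#'
#' @inheritParams train
#' @return List with `models`, `median_model`, and `dices` (best
#'   validation Dice per replicate).
#' @export
train_replicates <- function(train_pairs, val_pairs, cfg,
                             training_set_id = "train", verbose = FALSE) {
  n <- cfg$n_replicates
  models <- vector("list", n)
  for (r in seq_len(n)) {
    rcfg <- cfg
    rcfg$seed <- (cfg$seed + 7919L * r) %% 2147483647L
    models[[r]] <- train(train_pairs, val_pairs, rcfg,
                         training_set_id = training_set_id,
                         verbose = verbose)
  }
  dices <- vapply(models, function(m) m$best_val_dice, 0)
  list(models = models, median_model = models[[.median_index(dices)]],
       dices = dices)
}

# middle element after stable sort; lower middle for even counts, ties
# resolve to the earliest index
.median_index <- function(x) order(x)[(length(x) + 1L) %/% 2L]
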