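# Slide-grouped splitting, augmentation, the weighted loss, and training /
# prediction for the pluggable tile classifier. Tiles of one slide never
# cross split boundaries, mirroring the slide-grouped 60/20/20 design.

#' Training configuration
#'
#' Defaults echo the reference training schedule: 100 epochs, initial
#' learning rate 0.001 decaying by 0.9 every 5 epochs, Adam with momentum
#' (beta1) 0.9 and epsilon 1e-7, batches of 100 tiles, and a 1.5
#' misclassification penalty in the loss. `backbone = "tiny_cnn"` is the
#' CPU-sized default; `"inception_v3"` is accepted as a name but requires a
#' GPU-scale framework and is not provided here.
#'
#' @param epochs,lr0,lr_decay,decay_every,batch_size,loss_weight,seed see
#'   description.
#' @param backbone `"tiny_cnn"` or `"inception_v3"`.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 100L, lr0 = 0.001, lr_decay = 0.9,
                         decay_every = 5L, batch_size = 100L,
                         loss_weight = 1.5, seed = 1L,
                         backbone = c("tiny_cnn", "inception_v3")) {
  backbone <- match.arg(backbone)
  if (lr0 <= 0 || lr_decay <= 0) stop("learning rates must be positive")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(epochs = as.integer(epochs), lr0 = lr0, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every),
                 adam_beta1 = 0.9, adam_eps = 1e-7,
                 batch_size = as.integer(batch_size),
                 loss_weight = loss_weight, seed = as.integer(seed),
                 backbone = backbone),
            class = "train_config")
}

#' Slide-grouped stratified train/validation/test split
#'
#' Within each class, `floor(f_train * n)` slides go to training and
#' `floor(f_val * n)` to validation; the remainder is the test set (66 slides
#' per class yields 39/13/14). Assignment is random under `seed` and every
#' slide is assigned exactly once.
#'
#' @param manifest data.frame with `slide_id` and `class` columns.
#' @param fractions length-3 numeric summing to 1 (default `c(0.6, 0.2, 0.2)`).
#' @param seed integer.
#' @return `data.table` with columns `slide_id`, `class`, `split`
#'   (`train`/`val`/`test`).
#' @export
split_slides <- function(manifest, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three values summing to 1")
  m <- as.data.table(manifest)
  counts <- table(m$class)
  if (any(counts < 5L))
    stop("need at least 5 slides per class; got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  with_seed(seed, {
    out <- lapply(split(m$slide_id, m$class), function(ids) {
      ids <- sample(ids)
      n <- length(ids)
      n_tr <- floor(fractions[1] * n)
      n_va <- floor(fractions[2] * n)
      data.table::data.table(
        slide_id = ids,
        split = rep(c("train", "val", "test"),
                    c(n_tr, n_va, n - n_tr - n_va)))
    })
    asg <- data.table::rbindlist(out)
  })
  res <- merge(m[, c("slide_id", "class"), with = FALSE], asg, by = "slide_id")
  data.table::setkey(res, NULL)
  res[]
}

#' Random flip / right-angle rotation augmentation
#'
#' Draws a horizontal flip (p = 0.5), a vertical flip (p = 0.5) and a
#' rotation by `k * 90` degrees (`k` uniform on 0..3) from the current RNG
#' stream, and applies their composition. The pixel multiset is preserved
#' exactly.
#'
#' @param tile_pixels square `t x t x C` array.
#' @return transformed array of identical shape.
#' @export
augment_tile <- function(tile_pixels) {
  d <- dim(tile_pixels)
  if (d[1] != d[2]) stop("augment_tile expects a square tile")
  hflip <- runif(1) < 0.5
  vflip <- runif(1) < 0.5
  k <- sample(0:3, 1L)
  x <- tile_pixels
  if (hflip) x <- x[, d[2]:1, , drop = FALSE]
  if (vflip) x <- x[d[1]:1, , , drop = FALSE]
  if (k > 0) for (i in seq_len(k))                # 90 deg counter-clockwise
    x <- aperm(x, c(2L, 1L, 3L))[d[1]:1, , , drop = FALSE]
  x
}

#' Misclassification-weighted cross-entropy
#'
#' The per-example loss is `-log p_y`, multiplied by `w` whenever the
#' example's argmax prediction differs from its true class — both error
#' directions are penalized identically. `p_y` is floored at 1e-12 so the
#' loss stays finite.
#'
#' @param p numeric pair `(p_NS, p_S)` or an `n x 2` matrix of pairs.
#' @param y true class, `"NS"`/`"S"` (vector allowed).
#' @param w penalty factor for misclassified examples (default 1.5).
#' @return nonnegative loss value(s).
#' @export
weighted_loss <- function(p, y, w = 1.5) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
  yi <- ifelse(y == "S", 2L, 1L)
  py <- pmax(p[cbind(seq_len(nrow(p)), yi)], 1e-12)
  pred <- max.col(p, ties.method = "first")
  ifelse(pred != yi, w, 1) * (-log(py))
}

# Assemble a (55, 55, 3, N) batch from a list of full-resolution tiles.
prep_batch <- function(tile_list) {
  n <- length(tile_list)
  d0 <- dim(tile_list[[1]])
  x <- array(0, dim = c(d0[1], d0[2], 3L, n))
  for (i in seq_len(n)) x[, , , i] <- tile_list[[i]]
  if (d0[1] > 56L) x <- stem_downsample(x)
  x
}

#' Train the tile classifier
#'
#' Runs the augmented training loop of the reference schedule on the
#' `tiny_cnn` backbone: per-epoch shuffling, flip/rotation augmentation,
#' misclassification-weighted cross-entropy, Adam, and stepwise learning-rate
#' decay. Records per-epoch loss and accuracy curves (and validation curves
#' when a validation set is given).
#'
#' When a validation set is supplied, the returned model carries the
#' parameters of the epoch with the highest validation accuracy (earliest
#' epoch on ties) rather than the last epoch's: small-batch training on
#' weakly labelled tiles oscillates, and checkpoint selection on the
#' validation curve is the standard stabilizer.
#'
#' @param tiles list of normalized `220 x 220 x 3` (or pre-pooled
#'   `55 x 55 x 3`) arrays in `[0, 1]`.
#' @param labels character vector (`"NS"`/`"S"`), one per tile.
#' @param config a [train_config()].
#' @param val_tiles,val_labels optional validation tiles.
#' @param augment logical; disable to train on raw tiles.
#' @return a `tile_classifier`: list with `params`, `config`, `history`
#'   (data.frame epoch/lr/loss/accuracy and validation columns), `classes`,
#'   `best_epoch` (`NA` without a validation set).
#' @export
train_classifier <- function(tiles, labels, config = train_config(),
                             val_tiles = NULL, val_labels = NULL,
                             augment = TRUE) {
  if (config$backbone == "inception_v3")
    stop("the inception_v3 backbone needs a GPU-scale deep-learning ",
         "framework and is not bundled; use backbone = 'tiny_cnn'")
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class; both NS and S are required")
  y <- ifelse(labels == "S", 2L, 1L)
  with_seed(config$seed, {
    x_all <- prep_batch(tiles)
    params <- cnn_init()
    opt <- adam_init(params)
    n <- length(tiles)
    hist <- vector("list", config$epochs)
    xv <- if (!is.null(val_tiles)) prep_batch(val_tiles)
    yv <- if (!is.null(val_labels)) ifelse(val_labels == "S", 2L, 1L)
    best_val <- -Inf; best_params <- NULL; best_epoch <- NA_integer_
    for (epoch in seq_len(config$epochs)) {
      lr <- config$lr0 * config$lr_decay ^ ((epoch - 1L) %/% config$decay_every)
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- x_all[, , , idx, drop = FALSE]
        if (augment) for (j in seq_along(idx))
          xb[, , , j] <- augment_tile(xb[, , , j])
        yb <- y[idx]
        fwd <- cnn_forward(params, xb)
        losses <- weighted_loss(fwd$probs, c("NS", "S")[yb], config$loss_weight)
        ep_loss <- ep_loss + sum(losses)
        ep_correct <- ep_correct +
          sum(max.col(fwd$probs, ties.method = "first") == yb)
        grads <- cnn_backward(params, fwd, yb, config$loss_weight)
        upd <- adam_step(params, grads, opt, lr,
                         beta1 = config$adam_beta1, eps = config$adam_eps)
        params <- upd$params; opt <- upd$state
      }
      row <- data.frame(epoch = epoch, lr = lr, loss = ep_loss / n,
                        accuracy = ep_correct / n,
                        val_loss = NA_real_, val_accuracy = NA_real_)
      if (!is.null(xv)) {
        pv <- predict_prob_batched(params, xv)
        row$val_loss <- mean(weighted_loss(pv, c("NS", "S")[yv],
                                           config$loss_weight))
        row$val_accuracy <- mean(max.col(pv, ties.method = "first") == yv)
        if (row$val_accuracy > best_val) {
          best_val <- row$val_accuracy
          best_params <- params
          best_epoch <- epoch
        }
      }
      hist[[epoch]] <- row
    }
    structure(list(params = if (!is.null(best_params)) best_params else params,
                   config = config, history = do.call(rbind, hist),
                   classes = c("NS", "S"), best_epoch = best_epoch),
              class = "tile_classifier")
  })
}

#' @export
print.tile_classifier <- function(x, ...) {
  h <- utils::tail(x$history, 1L)
  cat(sprintf("<tile_classifier tiny_cnn> %d epochs  final loss %.4f  acc %.3f\n",
              nrow(x$history), h$loss, h$accuracy))
  invisible(x)
}

predict_prob_batched <- function(params, x, batch = 200L) {
  n <- dim(x)[4]
  out <- matrix(0, n, 2L)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    out[idx, ] <- cnn_forward(params, x[, , , idx, drop = FALSE],
                              keep_cache = FALSE)$probs
  }
  out
}

#' Per-tile class probabilities
#'
#' @param model a trained `tile_classifier`.
#' @param tiles list of normalized tile arrays (`[0, 1]` scale).
#' @param addresses optional data.frame with `slide_id`, `row`, `col` rows
#'   matching `tiles`; when given, a full prediction table is returned.
#' @return with `addresses`: `data.table` with
#'   `slide_id row col p_ns p_s label confidence` (ties at `p = 0.5` are
#'   called NS); otherwise an `n x 2` probability matrix.
#' @export
predict_tiles <- function(model, tiles, addresses = NULL) {
  if (!length(tiles)) stop("no tiles to predict")
  x <- prep_batch(tiles)
  probs <- predict_prob_batched(model$params, x)
  if (is.null(addresses)) return(probs)
  if (nrow(addresses) != length(tiles))
    stop("addresses and tiles differ in length")
  data.table::data.table(
    slide_id = addresses$slide_id, row = addresses$row, col = addresses$col,
    p_ns = probs[, 1], p_s = probs[, 2],
    label = ifelse(probs[, 2] > probs[, 1], "S", "NS"),
    confidence = pmax(probs[, 1], probs[, 2]))
}

#' Extract, normalize and predict the kept tiles of one slide
#'
#' Convenience wrapper used by the pipeline: extracts the kept tiles of a
#' filtered grid, Reinhard-normalizes the slide to `target_stats` (when
#' given), and returns the prediction table.
#'
#' @param model trained `tile_classifier`.
#' @param slide a [slide_image()].
#' @param grid the slide's filtered `tile_grid`.
#' @param target_stats optional reference [channel_stats()].
#' @return prediction `data.table` (one row per kept tile).
#' @export
predict_slide_tiles <- function(model, slide, grid, target_stats = NULL) {
  kept <- grid$tiles[grid$tiles$kept, ]
  if (!nrow(kept)) stop("slide ", slide$slide_id, " has no kept tiles")
  px <- slide$pixels
  if (!is.null(target_stats)) {
    src <- compute_channel_stats(px, tissue_mask(px))
    px <- reinhard_normalize(px, src, target_stats)
  }
  s2 <- slide_image(px, slide$slide_id, slide$microns_per_pixel,
                    slide$true_class)
  tiles <- lapply(seq_len(nrow(kept)), function(i)
    tile_pixels(s2, kept$row[i], kept$col[i], grid$tile_px))
  predict_tiles(model, tiles, kept[, c("slide_id", "row", "col")])
}
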