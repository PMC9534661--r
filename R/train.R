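# Training and prediction for DA-UNet models.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

slices_to_batch <- function(x, ids) {
  H <- dim(x)[1]; W <- dim(x)[2]
  matrix(as.vector(x[, , ids, drop = FALSE]), H * W * length(ids), 1L)
}

#' Train a DA-UNet on 2-D image/mask slices
#'
#' Minimises the classification cross-entropy loss with mini-batch Adam
#' (or plain gradient descent).  Inputs are standardised with the training
#' set's mean and standard deviation; the normalisation is stored in the
#' fit and re-applied at prediction time.
#'
#' @param x Numeric `H x W x n` array of intensity slices.
#' @param y Integer `H x W x n` array of gold labels in `0..num_classes-1`.
#' @param spec A [network_spec()].
#' @param epochs Number of passes over the training slices.
#' @param lr Learning rate.
#' @param batch_size Slices per mini-batch.
#' @param seed Seed controlling weight initialisation and shuffling.
#' @param optimizer `"adam"` (default) or `"sgd"` (plain gradient descent,
#'   useful when a monotone loss trace is wanted).
#' @param validation Optional list with elements `x` and `y` (same formats)
#'   scored with foreground Dice after every epoch.
#' @param bypass Internal list to freeze SE weights and/or attention
#'   coefficients at 1 (see block-bypass equivalence); leave empty.
#' @param verbose Print a line per epoch.
#' @return An object of class `daunet_fit`.
#' @export
train_daunet <- function(x, y, spec, epochs = 5L, lr = 1e-3, batch_size = 8L,
                         seed = 1L, optimizer = c("adam", "sgd"),
                         validation = NULL, bypass = list(),
                         verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  stopifnot(length(dim(x)) == 3L, all(dim(x) == dim(y)))
  H <- dim(x)[1]; W <- dim(x)[2]; n <- dim(x)[3]
  center <- mean(x)
  scale <- stats::sd(x)
  if (scale == 0) scale <- 1
  model <- build_daunet(spec, seed = seed)
  state <- if (optimizer == "adam") adam_init(model$params)
  yv <- as.integer(y)
  set.seed(seed + 1L)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (b0 in seq(1L, n, by = batch_size)) {
      ids <- ord[b0:min(b0 + batch_size - 1L, n)]
      xb <- (slices_to_batch(x, ids) - center) / scale
      tb <- as.integer(y[, , ids, drop = FALSE]) + 1L
      tape <- tp_new()
      fw <- daunet_forward(model, xb, H, W, length(ids), tape = tape,
                           training = TRUE, target = tb, bypass = bypass)
      tp_backward(tape, fw$loss)
      grads <- lapply(fw$param_nodes, function(nd) nd$grad)
      if (optimizer == "adam") {
        upd <- adam_step(model$params, grads, state, lr)
        model$params <- upd$params
        state <- upd$state
      } else {
        for (nm in names(model$params)) {
          if (!is.null(grads[[nm]]))
            model$params[[nm]] <- model$params[[nm]] - lr * grads[[nm]]
        }
      }
      losses <- c(losses, fw$loss$val)
    }
    row <- tibble::tibble(epoch = ep, loss = mean(losses),
                          val_dice = NA_real_)
    if (!is.null(validation)) {
      fit_tmp <- structure(list(model = model, center = center,
                                scale = scale, bypass = bypass),
                           class = "daunet_fit")
      pred <- predict(fit_tmp, validation$x)
      row$val_dice <- dice(confusion_counts(pred, validation$y))
    }
    if (verbose)
      message(sprintf("epoch %d: loss %.4f%s", ep, row$loss,
                      if (is.na(row$val_dice)) ""
                      else sprintf(", val Dice %.4f", row$val_dice)))
    hist[[ep]] <- row
  }
  structure(list(model = model, spec = spec,
                 history = do.call(rbind, hist), center = center,
                 scale = scale, seed = seed, epochs = epochs, lr = lr,
                 batch_size = batch_size, optimizer = optimizer,
                 bypass = bypass),
            class = "daunet_fit")
}

#' @export
print.daunet_fit <- function(x, ...) {
  print(x$model)
  last <- x$history[nrow(x$history), ]
  cat(sprintf("trained %d epoch(s), final loss %.4f%s\n", x$epochs,
              last$loss,
              if (is.na(last$val_dice)) ""
              else sprintf(", validation Dice %.4f", last$val_dice)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a DA-UNet fit
#' @param x A `daunet_fit`.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `loss`, `val_dice`.
#' @export
tidy.daunet_fit <- function(x, ...) x$history

#' One-row summary of a DA-UNet fit
#' @param x A `daunet_fit`.
#' @param ... Unused.
#' @return A tibble with the architecture, size and final-loss summary.
#' @export
glance.daunet_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(depth = x$spec$depth, base_channels = x$spec$base_channels,
                 use_se = x$spec$use_se, use_attention = x$spec$use_attention,
                 supervision_levels = x$spec$supervision_levels,
                 n_params = sum(vapply(x$model$params, length, 1L)),
                 epochs = x$epochs, final_loss = last$loss,
                 val_dice = last$val_dice)
}

# Symmetrically pad (with the fill value) so both extents are multiples of
# 2^depth; returns the padded array and the crop indices.
pad_for_depth <- function(x, depth, fill) {
  H <- dim(x)[1]; W <- dim(x)[2]
  m <- 2L^depth
  Hp <- as.integer(ceiling(H / m) * m)
  Wp <- as.integer(ceiling(W / m) * m)
  if (Hp == H && Wp == W)
    return(list(x = x, rows = seq_len(H), cols = seq_len(W)))
  oh <- (Hp - H) %/% 2L
  ow <- (Wp - W) %/% 2L
  out <- array(fill, c(Hp, Wp, dim(x)[3]))
  out[oh + seq_len(H), ow + seq_len(W), ] <- x
  list(x = out, rows = oh + seq_len(H), cols = ow + seq_len(W))
}

#' Predict segmentations for 2-D slices
#'
#' @param object A `daunet_fit`.
#' @param newdata `H x W` matrix or `H x W x n` array of intensities.
#'   Extents not divisible by `2^depth` are symmetrically padded with the
#'   training intensity mean and cropped back.
#' @param type `"label"` for integer class labels, `"prob"` for the
#'   `H x W x K (x n)` class-probability array.
#' @param batch_size Slices per forward batch.
#' @param ... Unused.
#' @return Labels or probabilities matching `newdata`'s spatial shape.
#' @export
predict.daunet_fit <- function(object, newdata, type = c("label", "prob"),
                               batch_size = 16L, ...) {
  type <- match.arg(type)
  single <- length(dim(newdata)) == 2L
  if (single) dim(newdata) <- c(dim(newdata), 1L)
  pad <- pad_for_depth(newdata, object$model$spec$depth, object$center)
  xs <- pad$x
  H <- dim(xs)[1]; W <- dim(xs)[2]; n <- dim(xs)[3]
  K <- object$model$spec$num_classes
  probs <- array(NA_real_, c(H, W, K, n))
  for (b0 in seq(1L, n, by = batch_size)) {
    ids <- b0:min(b0 + batch_size - 1L, n)
    xb <- (slices_to_batch(xs, ids) - object$center) / object$scale
    fw <- daunet_forward(object$model, xb, H, W, length(ids),
                         tape = NULL, training = FALSE,
                         bypass = object$bypass %||% list())
    probs[, , , ids] <- aperm(array(fw$probs, c(H, W, length(ids), K)),
                              c(1, 2, 4, 3))
  }
  probs <- probs[pad$rows, pad$cols, , , drop = FALSE]
  if (type == "prob") {
    if (single) dim(probs) <- dim(probs)[1:3]
    return(probs)
  }
  lab <- apply(probs, c(1, 2, 4), which.max) - 1L
  if (single) dim(lab) <- dim(lab)[1:2]
  storage.mode(lab) <- "integer"
  lab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment a 3-D volume slice-wise
#'
#' Applies a fitted 2-D network along one axis of a volume and reassembles
#' the per-slice labels into a mask aligned with the input grid.
#'
#' @param fit A `daunet_fit` (or any function taking an `H x W` matrix and
#'   returning an integer label matrix, accepted as a test double).
#' @param volume 3-D intensity array.
#' @param axis Axis along which slices are taken (default 3, axial).
#' @param batch_size Slices per forward batch.
#' @return Integer label mask with `volume`'s dimensions.
#' @export
predict_volume <- function(fit, volume, axis = 3L, batch_size = 16L) {
  stopifnot(length(dim(volume)) == 3L)
  perm <- list(c(2L, 3L, 1L), c(1L, 3L, 2L), c(1L, 2L, 3L))[[axis]]
  vol <- aperm(volume, perm)
  if (is.function(fit)) {
    mask <- array(0L, dim(vol))
    for (k in seq_len(dim(vol)[3])) mask[, , k] <- fit(vol[, , k])
  } else {
    mask <- predict(fit, vol, type = "label", batch_size = batch_size)
  }
  aperm(mask, order(perm))
}
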