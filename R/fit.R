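# Training drivers. Both fitters follow the same protocol: Adam with
# alpha = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-8, no learning-rate
# schedule, no early stopping, a fixed number of epochs, and the returned
# weights are the epoch checkpoint maximising the validation selection
# metric (patch accuracy / validation Dice).

prep_scan_pixels <- function(entry, contrast_enhancement) {
  scan <- entry$scan
  if (contrast_enhancement) scan <- contrast_enhance(scan)
  scan
}

#' Fit a patch-based boundary classifier
#'
#' Builds class-balanced training and validation patch sets from a
#' participant-split dataset (one patch per boundary per eligible column
#' plus one background patch), then trains the chosen architecture to
#' minimise cross-entropy. The returned model is the epoch checkpoint with
#' the highest validation accuracy.
#'
#' @param dataset an `oct_dataset` with `train` and `validation` splits.
#' @param architecture passed to [build_patch_model()].
#' @param spec a [patch_spec()].
#' @param crop a [crop_region()] restricting patch columns.
#' @param epochs number of training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam step size.
#' @param contrast_enhancement train on attenuation-compensated images.
#' @param column_stride sample patches from every `column_stride`-th
#'   eligible column (1 = every column).
#' @param seed RNG seed for initialisation, sampling and shuffling.
#' @param verbose print per-epoch metrics.
#' @return An object of class `oct_patch_model`.
#' @export
fit_patch_classifier <- function(dataset, architecture = "cifar_cnn",
                                 spec = patch_spec(), crop = crop_region(),
                                 epochs = 10L, batch_size = 64L, lr = 1e-3,
                                 contrast_enhancement = FALSE,
                                 column_stride = 1L,
                                 seed = 1L, verbose = FALSE) {
  stopifnot(inherits(dataset, "oct_dataset"))
  if (!length(dataset$train) || !length(dataset$validation))
    stop_octseg("dataset must have non-empty train and validation splits")
  with_seed(seed, {
    gather <- function(entries) {
      xs <- list(); ys <- list()
      for (e in entries) {
        scan <- prep_scan_pixels(e, contrast_enhancement)
        b <- e$boundaries
        if (column_stride > 1L) {
          keep <- seq(1L, attr(b, "width"), by = column_stride)
          drop <- setdiff(seq_len(attr(b, "width")), keep)
          b$ilm[drop] <- b$rpe[drop] <- b$csi[drop] <- NA_real_
        }
        p <- sample_training_patches(scan, b, spec, crop)
        xs[[length(xs) + 1L]] <- p$x
        ys[[length(ys) + 1L]] <- as.integer(p$label)
      }
      n <- sum(vapply(xs, function(a) dim(a)[4], 0))
      x <- array(0, c(spec$height, spec$width, 1L, n))
      off <- 0L
      for (a in xs) {
        k <- dim(a)[4]
        x[, , 1L, off + seq_len(k)] <- a
        off <- off + k
      }
      list(x = x, y = unlist(ys))
    }
    tr <- gather(dataset$train)
    va <- gather(dataset$validation)
    net <- build_patch_model(architecture, spec)
    opt <- adam_new(net$layers, lr = lr)
    n <- length(tr$y)
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric(), val_metric = numeric())
    best <- -Inf; best_loss <- Inf; best_snap <- NULL
    best_epoch <- NA_integer_
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tl <- 0; nb <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- tr$x[, , , idx, drop = FALSE]
        r <- patch_net_forward(net, xb, train = TRUE)
        lo <- patch_loss(r$y, tr$y[idx])
        seq_backward(net$layers, lo$dz, r$caches)
        adam_step(opt)
        tl <- tl + lo$loss; nb <- nb + 1
      }
      ev <- patch_eval(net, va$x, va$y, batch_size)
      log[ep, ] <- list(ep, tl / nb, ev$loss, ev$acc)
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f acc %.4f",
                        ep, tl / nb, ev$loss, ev$acc))
      # highest validation accuracy; ties resolved by lower validation loss
      if (ev$acc > best || (ev$acc == best && ev$loss < best_loss)) {
        best <- ev$acc; best_loss <- ev$loss
        best_snap <- snapshot_params(net$layers)
        best_epoch <- ep
      }
    }
    restore_params(net$layers, best_snap)
    structure(list(net = net, log = log, best_epoch = best_epoch,
                   crop = crop, spec = spec,
                   contrast_enhancement = contrast_enhancement,
                   architecture = architecture, seed = seed),
              class = c("oct_patch_model", "oct_model"))
  })
}

patch_eval <- function(net, x, y, batch_size = 256L) {
  n <- length(y)
  loss <- 0; correct <- 0; nb <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    r <- patch_net_forward(net, x[, , , idx, drop = FALSE], train = FALSE)
    lo <- patch_loss(r$y, y[idx])
    loss <- loss + lo$loss * length(idx)
    correct <- correct + sum(apply(lo$prob, 2, which.max) == y[idx])
    nb <- nb + length(idx)
  }
  list(loss = loss / nb, acc = correct / nb)
}

#' Fit a semantic segmentation network
#'
#' Trains a U-Net variant to label every pixel of a B-scan with its area
#' class (vitreous / retina / choroid / sclera), minimising the sum of
#' cross-entropy and Dice overlap loss. Columns lacking an annotation are
#' zeroed in the image and labelled vitreous in the mask. Each image is
#' flipped horizontally with 50% probability per epoch. The returned model
#' is the epoch checkpoint with the highest validation Dice.
#'
#' @param dataset an `oct_dataset` with `train` and `validation` splits; all
#'   scans must share one size divisible by `2^n_pool`.
#' @param variant passed to [build_semantic_model()].
#' @param epochs number of training epochs.
#' @param batch_size images per Adam step.
#' @param lr Adam step size.
#' @param contrast_enhancement train on attenuation-compensated images.
#' @param flip_augment horizontal flip augmentation (on by default).
#' @param dice_smooth Dice loss smoothing term.
#' @param base_filters,n_pool architecture size, see
#'   [build_semantic_model()].
#' @param seed RNG seed.
#' @param verbose print per-epoch metrics.
#' @return An object of class `oct_semantic_model`.
#' @export
fit_semantic_segmenter <- function(dataset, variant = "standard",
                                   epochs = 15L, batch_size = 2L, lr = 1e-3,
                                   contrast_enhancement = FALSE,
                                   flip_augment = TRUE, dice_smooth = 1,
                                   base_filters = 8L, n_pool = 4L,
                                   seed = 1L, verbose = FALSE) {
  stopifnot(inherits(dataset, "oct_dataset"))
  if (!length(dataset$train) || !length(dataset$validation))
    stop_octseg("dataset must have non-empty train and validation splits")
  with_seed(seed, {
    prep <- function(entries) lapply(entries, function(e) {
      scan <- prep_scan_pixels(e, contrast_enhancement)
      scan <- zero_missing_columns(scan, e$boundaries)
      mask <- boundaries_to_area_mask(e$boundaries, nrow(scan$pixels),
                                      ncol(scan$pixels))
      list(pixels = scan$pixels / 255, mask = mask)
    })
    tr <- prep(dataset$train)
    va <- prep(dataset$validation)
    net <- build_semantic_model(variant, base_filters = base_filters,
                                n_pool = n_pool)
    opt <- adam_new(net, lr = lr)
    n <- length(tr)
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric(), val_metric = numeric())
    best <- -Inf; best_snap <- NULL; best_epoch <- NA_integer_
    h <- nrow(tr[[1]]$pixels); w <- ncol(tr[[1]]$pixels)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tl <- 0; nb <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        k <- length(idx)
        x <- array(0, c(h, w, 1L, k))
        g <- array(0, c(h, w, 4L, k))
        for (j in seq_len(k)) {
          it <- tr[[idx[j]]]
          px <- it$pixels; mk <- it$mask
          if (flip_augment) {
            fl <- random_horizontal_flip(px, mk)
            px <- fl$pixels; mk <- fl$mask
          }
          x[, , 1L, j] <- px
          g[, , , j] <- one_hot_mask(mk)
        }
        r <- semantic_net_forward(net, x, train = TRUE)
        lo <- semantic_loss(r$y, g, dice_smooth)
        semantic_net_backward(net, lo$dz, r$caches)
        adam_step(opt)
        tl <- tl + lo$loss; nb <- nb + 1
      }
      ev <- semantic_eval(net, va, dice_smooth)
      log[ep, ] <- list(ep, tl / nb, ev$loss, ev$dice)
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f dice %.2f",
                        ep, tl / nb, ev$loss, ev$dice))
      if (ev$dice > best) {
        best <- ev$dice; best_snap <- snapshot_params(net)
        best_epoch <- ep
      }
    }
    restore_params(net, best_snap)
    structure(list(net = net, log = log, best_epoch = best_epoch,
                   variant = variant,
                   contrast_enhancement = contrast_enhancement,
                   seed = seed),
              class = c("oct_semantic_model", "oct_model"))
  })
}

# validation loss and mean Dice overlap percentage (4 classes, from the
# network's argmax labelling)
semantic_eval <- function(net, items, dice_smooth = 1) {
  loss <- 0; dice <- 0
  for (it in items) {
    x <- array(it$pixels, c(dim(it$pixels), 1L, 1L))
    g <- one_hot_mask(it$mask)
    r <- semantic_net_forward(net, x, train = FALSE)
    lo <- semantic_loss(r$y, g, dice_smooth)
    loss <- loss + lo$loss
    lab <- apply(array(lo$prob, dim(lo$prob)[1:3]), c(1, 2), which.max) - 1L
    ds <- vapply(0:3, function(c) {
      a <- lab == c; b <- it$mask == c
      na <- sum(a); nb <- sum(b)
      if (na + nb == 0) 100 else 200 * sum(a & b) / (na + nb)
    }, 0)
    dice <- dice + mean(ds)
  }
  list(loss = loss / length(items), dice = dice / length(items))
}

# --------------------------------------------------------------------------
# S3 methods for fitted models

#' @export
print.oct_model <- function(x, ...) {
  kind <- if (inherits(x, "oct_patch_model"))
    sprintf("patch-based (%s, %dx%d patches)", x$architecture,
            x$spec$height, x$spec$width)
  else sprintf("semantic (%s U-Net)", x$variant)
  cat(sprintf("<%s> %s\n", class(x)[1], kind))
  cat(sprintf("  parameters: %s; best epoch %d/%d (val metric %.4f)\n",
              format(count_params(if (is.null(x$net$layers)) x$net
                                  else x$net$layers), big.mark = ","),
              x$best_epoch, nrow(x$log), max(x$log$val_metric)))
  if (x$contrast_enhancement) cat("  input: contrast enhanced\n")
  invisible(x)
}

#' @export
summary.oct_model <- function(object, ...) {
  print(object)
  cat("\nTraining log:\n")
  print(object$log, row.names = FALSE)
  invisible(object$log)
}

#' @export
plot.oct_model <- function(x, ...) {
  matplot(x$log$epoch, cbind(x$log$train_loss, x$log$val_loss),
          type = "l", lty = 1, col = c("black", "red"),
          xlab = "epoch", ylab = "loss", ...)
  legend("topright", c("train", "validation"), lty = 1,
         col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Number of trainable parameters of a fitted model
#' @param model an `oct_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  if (inherits(model, "oct_patch_model")) count_params(model$net$layers)
  else if (inherits(model, "oct_semantic_model")) count_params(model$net)
  else if (inherits(model, "patch_net")) count_params(model$layers)
  else if (inherits(model, "semantic_net")) count_params(model)
  else stop_octseg("not a model object")
}

#' @export
predict.oct_patch_model <- function(object, scan,
                                    type = c("boundaries", "maps"), ...) {
  type <- match.arg(type)
  if (object$contrast_enhancement) scan <- contrast_enhance(scan)
  maps <- patch_probability_maps(object$net, scan, object$crop, ...)
  if (type == "maps") return(maps)
  maps_to_boundaries(maps)
}

#' @export
predict.oct_semantic_model <- function(object, scan,
                                       type = c("boundaries", "maps",
                                                "area"), ...) {
  type <- match.arg(type)
  if (object$contrast_enhancement) scan <- contrast_enhance(scan)
  probs <- semantic_net_predict(object$net, scan$pixels)
  if (type == "area") return(probs)
  maps <- semantic_boundary_maps(probs, ...)
  if (type == "maps") return(maps)
  maps_to_boundaries(maps)
}
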