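# Softmax, cross-entropy and Dice overlap loss (with gradients w.r.t. logits).

# per-pixel softmax over the channel axis of (H, W, C, N)
softmax_channels <- function(z) {
  d <- dim(z)
  m <- z[, , 1, , drop = FALSE]
  for (c in seq_len(d[3])[-1]) m <- pmax(m, z[, , c, , drop = FALSE])
  e <- exp(z - array(m[, , rep(1, d[3]), , drop = FALSE], d))
  s <- e[, , 1, , drop = FALSE]
  for (c in seq_len(d[3])[-1]) s <- s + e[, , c, , drop = FALSE]
  e / array(s[, , rep(1, d[3]), , drop = FALSE], d)
}

# column-wise softmax of a (C, N) logit matrix
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# one-hot encode an integer area mask (H, W) over `classes` labels 0-based
one_hot_mask <- function(mask, classes = 4L) {
  d <- dim(mask)
  g <- array(0, c(d[1], d[2], classes, 1L))
  for (c in seq_len(classes)) g[, , c, 1L] <- mask == (c - 1L)
  g
}

#' Dice overlap loss
#'
#' `1 - mean_c (2 * sum(p_c * g_c) + s) / (sum(p_c^2) + sum(g_c^2) + s)`
#' over the four area classes, with smoothing `s` (default 1). The squared
#' denominator follows the V-Net formulation of the Dice loss. Zero (as
#' `s -> 0`) exactly when the prediction equals the one-hot target; bounded
#' by 1. Classes are equally weighted.
#'
#' @param prob per-pixel class probability array `(H, W, C, N)`.
#' @param target one-hot target of the same shape.
#' @param smooth smoothing term `s`.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_overlap_loss <- function(prob, target, smooth = 1) {
  d <- dim(prob)
  if (!identical(d, dim(target)))
    stop_octseg("prediction and target shapes differ")
  ratios <- vapply(seq_len(d[3]), function(c) {
    p <- prob[, , c, , drop = FALSE]
    g <- target[, , c, , drop = FALSE]
    (2 * sum(p * g) + smooth) / (sum(p * p) + sum(g * g) + smooth)
  }, 0)
  1 - mean(ratios)
}

# gradient of dice_overlap_loss w.r.t. prob
dice_loss_grad <- function(prob, target, smooth = 1) {
  d <- dim(prob)
  grad <- array(0, d)
  nc <- d[3]
  for (c in seq_len(nc)) {
    p <- prob[, , c, , drop = FALSE]
    g <- target[, , c, , drop = FALSE]
    num <- 2 * sum(p * g) + smooth
    den <- sum(p * p) + sum(g * g) + smooth
    grad[, , c, ] <- -(2 * g * den - num * 2 * p) / (nc * den^2)
  }
  grad
}

# combined semantic loss: cross-entropy + Dice, with gradient w.r.t. logits
semantic_loss <- function(logits, target, dice_smooth = 1, use_dice = TRUE) {
  d <- dim(logits)
  p <- softmax_channels(logits)
  npix <- d[1] * d[2] * d[4]
  ce <- -sum(target * log(pmax(p, 1e-12))) / npix
  dz <- (p - target) / npix
  dl <- 0
  if (use_dice) {
    dl <- dice_overlap_loss(p, target, dice_smooth)
    dp <- dice_loss_grad(p, target, dice_smooth)
    # chain through the softmax Jacobian per pixel
    inner <- dp[, , 1, , drop = FALSE] * p[, , 1, , drop = FALSE]
    for (c in seq_len(d[3])[-1])
      inner <- inner + dp[, , c, , drop = FALSE] * p[, , c, , drop = FALSE]
    dz <- dz + p * (dp - array(inner[, , rep(1, d[3]), , drop = FALSE], d))
  }
  list(loss = ce + dl, ce = ce, dice = dl, dz = dz, prob = p)
}

# patch classification loss: cross-entropy over a (4, N) logit matrix with
# integer labels in 1..4
patch_loss <- function(logits, labels) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  idx <- cbind(labels, seq_len(n))
  ce <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = ce, dz = g / n, prob = p)
}
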