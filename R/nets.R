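#' Build a patch classification network
#'
#' Three architectures are available, all ending in a 4-way softmax over
#' (ILM, RPE, CSI, BG):
#' * `cifar_cnn` — three 5x5 convolution + 2x2 max-pool stages (32, 32, 64
#'   filters) and two fully-connected stages; the classic small image
#'   classifier.
#' * `complex_cnn` — a deeper, wider CNN with five 3x3 convolution stages
#'   (64, 64, 128, 128, 256 filters), three pools and a wide
#'   fully-connected stage; by far the most parameters.
#' * `renet_rnn` — ReNet-style stacked bidirectional recurrent sweeps over
#'   non-overlapping 2x2 receptive-field tiles, first vertical then
#'   horizontal (32 filters per direction), followed by a fully-connected
#'   softmax; the fewest parameters.
#'
#' ReLU activations throughout; no dropout in the CNNs, a light dropout
#' between the recurrent sweeps of the RNN. Weights are drawn from the
#' current RNG state (He-scaled normals), so builds are reproducible under
#' `set.seed()`.
#'
#' @param architecture one of `"cifar_cnn"`, `"complex_cnn"`, `"renet_rnn"`.
#' @param spec a [patch_spec()]; both dimensions must be even (and divisible
#'   by 8 for the CNNs, which pool three times).
#' @param rnn_filters filters per direction for the recurrent sweeps.
#' @param rnn_dropout dropout rate between the recurrent sweeps.
#' @return A list of class `patch_net` with the layer stack.
#' @export
build_patch_model <- function(architecture = c("cifar_cnn", "complex_cnn",
                                               "renet_rnn"),
                              spec = patch_spec(),
                              rnn_filters = 32L, rnn_dropout = 0.2) {
  architecture <- match.arg(architecture)
  stopifnot(inherits(spec, "patch_spec"))
  h <- spec$height; w <- spec$width
  if (h %% 2L || w %% 2L) stop_octseg("patch dimensions must be even")
  layers <- switch(architecture,
    cifar_cnn = {
      if (h %% 8L || w %% 8L)
        stop_octseg("CNN patch dimensions must be divisible by 8")
      list(nn_conv(5, 5, 1, 32), nn_relu(), nn_pool(),
           nn_conv(5, 5, 32, 32), nn_relu(), nn_pool(),
           nn_conv(5, 5, 32, 64), nn_relu(), nn_pool(),
           nn_flatten(),
           nn_fc((h / 8) * (w / 8) * 64, 64), nn_relu(),
           nn_fc(64, 4))
    },
    complex_cnn = {
      if (h %% 8L || w %% 8L)
        stop_octseg("CNN patch dimensions must be divisible by 8")
      list(nn_conv(3, 3, 1, 64), nn_relu(),
           nn_conv(3, 3, 64, 64), nn_relu(), nn_pool(),
           nn_conv(3, 3, 64, 128), nn_relu(),
           nn_conv(3, 3, 128, 128), nn_relu(), nn_pool(),
           nn_conv(3, 3, 128, 256), nn_relu(), nn_pool(),
           nn_flatten(),
           nn_fc((h / 8) * (w / 8) * 256, 256), nn_relu(),
           nn_fc(256, 4))
    },
    renet_rnn = {
      list(nn_tile(2, 2),
           nn_rnn("v", 4, rnn_filters),
           nn_dropout(rnn_dropout),
           nn_rnn("h", 2 * rnn_filters, rnn_filters),
           nn_dropout(rnn_dropout),
           nn_flatten(),
           nn_fc((h / 2) * (w / 2) * 2 * rnn_filters, 4))
    })
  structure(list(architecture = architecture, spec = spec, layers = layers,
                 n_classes = 4L),
            class = "patch_net")
}

# forward pass of a patch network; x is (h, w, 1, N), returns (4, N) logits
patch_net_forward <- function(net, x, train = FALSE) {
  seq_forward(net$layers, x, train)
}

#' Per-class probabilities from a patch network
#'
#' @param net a `patch_net`.
#' @param x patch array `(height, width, 1, N)` with intensities in `[0, 1]`.
#' @return A `(4, N)` matrix of class probabilities (columns sum to 1).
#' @export
patch_net_predict <- function(net, x) {
  softmax_cols(seq_forward(net$layers, x, FALSE)$y)
}

#' Build a semantic segmentation network (U-Net variants)
#'
#' An encoder-decoder with skip connections: `n_pool` pooling and
#' up-sampling levels, `base_filters` filters in the first encoder block
#' doubled at each pooling level (8, 16, 32, 64 and 128 at the bottleneck
#' with the defaults), zero-padded 3x3 convolutions so input and output
#' sizes match, batch normalisation before every ReLU, and 50% dropout at
#' the bottleneck output. The per-pixel head is a 1x1 convolution to the 4
#' area classes (vitreous, retina, choroid, sclera).
#'
#' Variants:
#' * `standard` — plain U-Net.
#' * `residual` — identity shortcuts across every convolution block
#'   (1x1 projections where the channel count changes).
#' * `rnn_bottleneck` — the bottleneck convolutions are replaced by
#'   bidirectional recurrent sweeps, vertical then horizontal.
#' * `cse` / `sse` / `scse` — squeeze-and-excitation blocks (channel,
#'   spatial, or their element-wise combination) after every block.
#' * `combined` — residual + RNN bottleneck + scSE.
#'
#' @param variant one of standard, residual, rnn_bottleneck, cse, sse, scse,
#'   combined.
#' @param base_filters filters in the first encoder block (default 8).
#' @param n_pool number of pooling levels (default 4).
#' @param dropout_bottleneck dropout rate at the bottleneck output.
#' @param n_classes number of area classes.
#' @param scse_combine how scSE merges its two gates: `"max"` (element-wise
#'   maximum, default) or `"add"`.
#' @return A list of class `semantic_net`.
#' @export
build_semantic_model <- function(variant = c("standard", "residual",
                                             "rnn_bottleneck", "cse", "sse",
                                             "scse", "combined"),
                                 base_filters = 8L, n_pool = 4L,
                                 dropout_bottleneck = 0.5, n_classes = 4L,
                                 scse_combine = "max") {
  variant <- match.arg(variant)
  residual <- variant %in% c("residual", "combined")
  se <- switch(variant, cse = "cse", sse = "sse", scse = "scse",
               combined = "scse", NULL)
  rnn_bn <- variant %in% c("rnn_bottleneck", "combined")
  filters <- base_filters * 2L^(0:n_pool)      # encoder progression
  enc <- list(); cin <- 1L
  for (lv in seq_len(n_pool)) {
    enc[[lv]] <- nn_block(cin, filters[lv], residual, se, scse_combine)
    cin <- filters[lv]
  }
  cb <- filters[n_pool + 1L]
  bottleneck <- if (rnn_bn) {
    bl <- list(rnn1 = nn_rnn("v", cin, cb %/% 2L),
               rnn2 = nn_rnn("h", cb, cb %/% 2L))
    if (!is.null(se)) bl$se <- switch(se, cse = nn_cse(cb), sse = nn_sse(cb),
                                      scse = nn_scse(cb, scse_combine))
    bl
  } else {
    list(block = nn_block(cin, cb, residual, se, scse_combine))
  }
  upconv <- list(); dec <- list()
  for (lv in seq.int(n_pool, 1L)) {
    cf <- filters[lv]
    upconv[[lv]] <- list(conv = nn_conv(3, 3, 2L * cf, cf), bn = nn_bn(cf))
    dec[[lv]] <- nn_block(2L * cf, cf, residual, se, scse_combine)
  }
  structure(
    list(variant = variant, base_filters = as.integer(base_filters),
         n_pool = as.integer(n_pool), n_classes = as.integer(n_classes),
         filters = filters,
         enc = enc, pools = lapply(seq_len(n_pool), function(i) nn_pool()),
         bottleneck = bottleneck, dropout = nn_dropout(dropout_bottleneck),
         ups = lapply(seq_len(n_pool), function(i) nn_up()),
         upconv = upconv, dec = dec,
         head = nn_conv(1, 1, base_filters, n_classes)),
    class = "semantic_net")
}

# forward pass; x is (H, W, 1, N) with H, W divisible by 2^n_pool
semantic_net_forward <- function(net, x, train = FALSE) {
  d <- dim(x)
  div <- 2L^net$n_pool
  if (d[1] %% div || d[2] %% div)
    stop_octseg(sprintf(
      "input %dx%d not divisible by %d; pad to %dx%d",
      d[1], d[2], div, ceiling(d[1] / div) * div, ceiling(d[2] / div) * div))
  caches <- list(enc = list(), pool = list(), bott = list(), up = list(),
                 upc = list(), cat = list(), dec = list())
  skips <- list()
  cur <- x
  for (lv in seq_len(net$n_pool)) {
    r <- ly_forward(net$enc[[lv]], cur, train)
    skips[[lv]] <- r$y
    caches$enc[[lv]] <- r$cache
    rp <- ly_forward(net$pools[[lv]], r$y, train)
    caches$pool[[lv]] <- rp$cache
    cur <- rp$y
  }
  if (!is.null(net$bottleneck$block)) {
    rb <- ly_forward(net$bottleneck$block, cur, train)
    caches$bott$block <- rb$cache
    cur <- rb$y
  } else {
    r1 <- ly_forward(net$bottleneck$rnn1, cur, train)
    caches$bott$rnn1 <- r1$cache
    r2 <- ly_forward(net$bottleneck$rnn2, r1$y, train)
    caches$bott$rnn2 <- r2$cache
    cur <- r2$y
    if (!is.null(net$bottleneck$se)) {
      rs <- ly_forward(net$bottleneck$se, cur, train)
      caches$bott$se <- rs$cache
      cur <- rs$y
    }
  }
  rd <- ly_forward(net$dropout, cur, train)
  caches$drop <- rd$cache
  cur <- rd$y
  for (lv in seq.int(net$n_pool, 1L)) {
    ru <- ly_forward(net$ups[[lv]], cur, train)
    caches$up[[lv]] <- ru$cache
    rc <- ly_forward(net$upconv[[lv]]$conv, ru$y, train)
    rb <- ly_forward(net$upconv[[lv]]$bn, rc$y, train)
    mask <- rb$y > 0
    a <- rb$y * mask
    caches$upc[[lv]] <- list(conv = rc$cache, bn = rb$cache, mask = mask)
    skip <- skips[[lv]]
    cat_in <- abind4(skip, a)
    caches$cat[[lv]] <- dim(skip)[3]
    rdec <- ly_forward(net$dec[[lv]], cat_in, train)
    caches$dec[[lv]] <- rdec$cache
    cur <- rdec$y
  }
  rh <- ly_forward(net$head, cur, train)
  caches$head <- rh$cache
  list(y = rh$y, caches = caches)
}

semantic_net_backward <- function(net, dy, caches) {
  dy <- ly_backward(net$head, dy, caches$head)
  dskips <- vector("list", net$n_pool)
  for (lv in seq_len(net$n_pool)) {
    dcat <- ly_backward(net$dec[[lv]], dy, caches$dec[[lv]])
    csk <- caches$cat[[lv]]
    dskips[[lv]] <- dcat[, , seq_len(csk), , drop = FALSE]
    da <- dcat[, , csk + seq_len(dim(dcat)[3] - csk), , drop = FALSE]
    da <- da * caches$upc[[lv]]$mask
    db <- ly_backward(net$upconv[[lv]]$bn, da, caches$upc[[lv]]$bn)
    dc <- ly_backward(net$upconv[[lv]]$conv, db, caches$upc[[lv]]$conv)
    dy <- ly_backward(net$ups[[lv]], dc, caches$up[[lv]])
  }
  dy <- ly_backward(net$dropout, dy, caches$drop)
  if (!is.null(net$bottleneck$block)) {
    dy <- ly_backward(net$bottleneck$block, dy, caches$bott$block)
  } else {
    if (!is.null(net$bottleneck$se))
      dy <- ly_backward(net$bottleneck$se, dy, caches$bott$se)
    dy <- ly_backward(net$bottleneck$rnn2, dy, caches$bott$rnn2)
    dy <- ly_backward(net$bottleneck$rnn1, dy, caches$bott$rnn1)
  }
  for (lv in seq.int(net$n_pool, 1L)) {
    dpool <- ly_backward(net$pools[[lv]], dy, caches$pool[[lv]])
    dpool <- dpool + dskips[[lv]]
    dy <- ly_backward(net$enc[[lv]], dpool, caches$enc[[lv]])
  }
  dy
}

# concatenate two (H, W, C, N) arrays along the channel axis
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Per-pixel area class probabilities from a semantic network
#'
#' @param net a `semantic_net`.
#' @param pixels H x W image matrix with intensities in `[0, 255]`.
#' @return An `(H, W, 4)` probability array (per-pixel sums are 1).
#' @export
semantic_net_predict <- function(net, pixels) {
  x <- array(pixels / 255, c(nrow(pixels), ncol(pixels), 1L, 1L))
  p <- softmax_channels(semantic_net_forward(net, x, FALSE)$y)
  array(p, dim(p)[1:3])
}
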