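# Minimal CPU neural-network engine used by both segmentation pipelines.
#
# Layers are environments holding parameters (l$p), accumulated gradients
# (l$g) and state (l$s). Activations in convolutional layers are 4-d arrays
# (H, W, C, N); fully-connected layers use (D, N) matrices. `ly_forward()`
# returns the output plus a cache which `ly_backward()` consumes; gradients
# accumulate into the layer until the optimiser step clears them.
# All random draws (initialisation, dropout) use R's RNG, so training is
# reproducible under set.seed().

new_layer <- function(type, p = list(), s = list(), children = list()) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$p <- p
  l$g <- lapply(p, function(a) array(0, dim(a) %||% length(a)))
  l$s <- s
  l$children <- children
  class(l) <- "octseg_layer"
  l
}

he_init <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

nn_conv <- function(kh, kw, cin, cout) {
  new_layer("conv",
            p = list(w = he_init(c(kh, kw, cin, cout), kh * kw * cin),
                     b = numeric(cout)))
}

nn_fc <- function(din, dout) {
  new_layer("fc", p = list(w = matrix(rnorm(dout * din, 0, sqrt(2 / din)),
                                      dout, din),
                           b = numeric(dout)))
}

nn_bn <- function(c) {
  new_layer("bn", p = list(gamma = rep(1, c), beta = numeric(c)),
            s = list(run_mean = numeric(c), run_var = rep(1, c),
                     momentum = 0.9, eps = 1e-5))
}

nn_relu <- function() new_layer("relu")
nn_pool <- function() new_layer("pool")
nn_up <- function() new_layer("up")
nn_flatten <- function() new_layer("flatten")
nn_dropout <- function(rate) new_layer("dropout", s = list(rate = rate))

# bidirectional recurrent sweep over rows ("v") or columns ("h")
nn_rnn <- function(direction, cin, filters) {
  mk <- function() list(
    wx = matrix(rnorm(filters * cin, 0, sqrt(1 / cin)), filters, cin),
    wh = matrix(rnorm(filters * filters, 0, 0.5 * sqrt(1 / filters)),
                filters, filters),
    b = numeric(filters))
  d1 <- mk(); d2 <- mk()
  new_layer("rnn",
            p = list(wx1 = d1$wx, wh1 = d1$wh, b1 = d1$b,
                     wx2 = d2$wx, wh2 = d2$wh, b2 = d2$b),
            s = list(direction = direction, f = filters, cin = cin))
}

# space-to-depth tiling for ReNet-style sweeps over rf x rf receptive fields
nn_tile <- function(rh, rw) new_layer("tile", s = list(rh = rh, rw = rw))

# channel squeeze-and-excitation: global pool -> FC -> ReLU -> FC -> sigmoid
nn_cse <- function(c, reduction = 2) {
  cr <- max(1L, c %/% reduction)
  new_layer("cse",
            p = list(w1 = matrix(rnorm(cr * c, 0, sqrt(2 / c)), cr, c),
                     b1 = numeric(cr),
                     w2 = matrix(rnorm(c * cr, 0, sqrt(2 / cr)), c, cr),
                     b2 = numeric(c)))
}

# spatial squeeze-and-excitation: 1x1 conv -> sigmoid spatial gate
nn_sse <- function(c) {
  new_layer("sse", p = list(w = rnorm(c, 0, sqrt(2 / c)), b = 0))
}

nn_scse <- function(c, combine = "max") {
  new_layer("scse", s = list(combine = combine),
            children = list(cse = nn_cse(c), sse = nn_sse(c)))
}

# two 3x3 conv stages with batch-norm + ReLU; optional identity shortcut
# (1x1 projection when channels change) and optional SE block on the output
nn_block <- function(cin, cout, residual = FALSE, se = NULL,
                     se_combine = "max") {
  ch <- list(conv1 = nn_conv(3, 3, cin, cout), bn1 = nn_bn(cout),
             conv2 = nn_conv(3, 3, cout, cout), bn2 = nn_bn(cout))
  if (residual && cin != cout) ch$proj <- nn_conv(1, 1, cin, cout)
  if (!is.null(se))
    ch$se <- switch(se, cse = nn_cse(cout), sse = nn_sse(cout),
                    scse = nn_scse(cout, se_combine),
                    stop_octseg("unknown SE variant '", se, "'"))
  new_layer("block", s = list(residual = residual), children = ch)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---------------------------------------------------------------------------
# forward / backward dispatch

ly_forward <- function(l, x, train = FALSE) {
  switch(l$type,
    conv = list(y = .conv2d_forward(x, l$p$w, l$p$b), cache = list(x = x)),
    fc = list(y = sweep(l$p$w %*% x, 1, l$p$b, "+"), cache = list(x = x)),
    relu = {
      y <- x * (x > 0)
      list(y = y, cache = list(mask = x > 0))
    },
    bn = bn_forward(l, x, train),
    pool = {
      r <- .maxpool2_forward(x)
      list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)))
    },
    up = {
      d <- dim(x)
      y <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
             drop = FALSE]
      list(y = y, cache = list(xdim = d))
    },
    flatten = {
      d <- dim(x)
      list(y = matrix(x, prod(d[1:3]), d[4]), cache = list(xdim = d))
    },
    dropout = {
      if (train && l$s$rate > 0) {
        keep <- 1 - l$s$rate
        mask <- array((runif(length(x)) < keep) / keep, dim(x))
        list(y = x * mask, cache = list(mask = mask))
      } else list(y = x, cache = list(mask = NULL))
    },
    tile = tile_forward(l, x),
    rnn = rnn_forward(l, x),
    cse = cse_forward(l, x),
    sse = sse_forward(l, x),
    scse = scse_forward(l, x, train),
    block = block_forward(l, x, train),
    stop_octseg("unknown layer type '", l$type, "'"))
}

ly_backward <- function(l, dy, cache) {
  switch(l$type,
    conv = {
      r <- .conv2d_backward(cache$x, l$p$w, dy)
      l$g$w <- l$g$w + r$dw
      l$g$b <- l$g$b + r$db
      r$dx
    },
    fc = {
      l$g$w <- l$g$w + dy %*% t(cache$x)
      l$g$b <- l$g$b + rowSums(dy)
      t(l$p$w) %*% dy
    },
    relu = dy * cache$mask,
    bn = bn_backward(l, dy, cache),
    pool = .maxpool2_backward(dy, cache$idx, as.integer(cache$xdim)),
    up = {
      d <- cache$xdim
      ro <- seq(1, 2 * d[1], by = 2)
      co <- seq(1, 2 * d[2], by = 2)
      dy[ro, co, , , drop = FALSE] + dy[ro + 1, co, , , drop = FALSE] +
        dy[ro, co + 1, , , drop = FALSE] + dy[ro + 1, co + 1, , , drop = FALSE]
    },
    flatten = array(dy, cache$xdim),
    dropout = if (is.null(cache$mask)) dy else dy * cache$mask,
    tile = tile_backward(l, dy, cache),
    rnn = rnn_backward(l, dy, cache),
    cse = cse_backward(l, dy, cache),
    sse = sse_backward(l, dy, cache),
    scse = scse_backward(l, dy, cache),
    block = block_backward(l, dy, cache),
    stop_octseg("unknown layer type '", l$type, "'"))
}

# ---------------------------------------------------------------------------
# batch normalisation (per channel over H, W, N)

bn_forward <- function(l, x, train) {
  d <- dim(x)
  C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)   # (H*W*N) x C
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    l$s$run_mean <- l$s$momentum * l$s$run_mean + (1 - l$s$momentum) * mu
    l$s$run_var <- l$s$momentum * l$s$run_var + (1 - l$s$momentum) * v
  } else {
    mu <- l$s$run_mean
    v <- l$s$run_var
  }
  istd <- 1 / sqrt(v + l$s$eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, istd, "*")
  ym <- sweep(sweep(xhat, 2, l$p$gamma, "*"), 2, l$p$beta, "+")
  y <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(y = y, cache = list(xhat = xhat, istd = istd, d = d, train = train))
}

bn_backward <- function(l, dy, cache) {
  d <- cache$d
  C <- d[3]
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = C)
  xhat <- cache$xhat
  l$g$gamma <- l$g$gamma + colSums(dym * xhat)
  l$g$beta <- l$g$beta + colSums(dym)
  dxhat <- sweep(dym, 2, l$p$gamma, "*")
  if (cache$train) {
    m <- nrow(dym)
    t1 <- colSums(dxhat)
    t2 <- colSums(dxhat * xhat)
    dxm <- sweep(dxhat, 2, t1 / m, "-") - sweep(xhat, 2, t2 / m, "*")
    dxm <- sweep(dxm, 2, cache$istd, "*")
  } else {
    dxm <- sweep(dxhat, 2, cache$istd, "*")
  }
  aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
}

# ---------------------------------------------------------------------------
# space-to-depth tiling

tile_forward <- function(l, x) {
  d <- dim(x)
  rh <- l$s$rh; rw <- l$s$rw
  if (d[1] %% rh || d[2] %% rw)
    stop_octseg("input size not divisible by the receptive field")
  ht <- d[1] %/% rh; wt <- d[2] %/% rw
  a <- array(x, c(rh, ht, rw, wt, d[3], d[4]))
  y <- array(aperm(a, c(2, 4, 1, 3, 5, 6)), c(ht, wt, rh * rw * d[3], d[4]))
  list(y = y, cache = list(xdim = d))
}

tile_backward <- function(l, dy, cache) {
  d <- cache$xdim
  rh <- l$s$rh; rw <- l$s$rw
  ht <- d[1] %/% rh; wt <- d[2] %/% rw
  a <- array(dy, c(ht, wt, rh, rw, d[3], d[4]))
  array(aperm(a, c(3, 1, 4, 2, 5, 6)), d)
}

# ---------------------------------------------------------------------------
# bidirectional recurrent sweep: h_t = tanh(Wx x_t + Wh h_{t-1} + b),
# run top-to-bottom and bottom-to-top (or left/right), outputs concatenated
# along the feature axis.

rnn_perm <- function(direction) {
  if (direction == "v") c(3, 2, 4, 1) else c(3, 1, 4, 2)
}

rnn_forward <- function(l, x) {
  d <- dim(x)
  C <- d[3]; f <- l$s$f
  pm <- rnn_perm(l$s$direction)
  TT <- d[pm[4]]
  B <- d[pm[2]] * d[pm[3]]
  xa <- array(aperm(x, pm), c(C, B, TT))
  run <- function(wx, wh, b, ts) {
    hs <- array(0, c(f, B, TT))
    hprev <- matrix(0, f, B)
    for (t in ts) {
      hprev <- tanh(wx %*% xa_t(xa, t) + wh %*% hprev + b)
      hs[, , t] <- hprev
    }
    hs
  }
  hs1 <- run(l$p$wx1, l$p$wh1, l$p$b1, seq_len(TT))
  hs2 <- run(l$p$wx2, l$p$wh2, l$p$b2, rev(seq_len(TT)))
  ya <- array(0, c(2 * f, B, TT))
  ya[seq_len(f), , ] <- hs1
  ya[f + seq_len(f), , ] <- hs2
  # invert the permutation
  yp <- array(ya, c(2 * f, d[pm[2]], d[pm[3]], TT))
  inv <- order(pm)
  y <- aperm(yp, inv)
  list(y = y, cache = list(xa = xa, hs1 = hs1, hs2 = hs2, d = d))
}

rnn_backward <- function(l, dy, cache) {
  d <- cache$d
  C <- d[3]; f <- l$s$f
  pm <- rnn_perm(l$s$direction)
  TT <- d[pm[4]]
  B <- d[pm[2]] * d[pm[3]]
  dya <- array(aperm(dy, pm), c(2 * f, B, TT))
  dxa <- array(0, c(C, B, TT))
  bptt <- function(hs, wx, wh, ts, dslice, gw, gh, gb) {
    dwx <- l$g[[gw]]; dwh <- l$g[[gh]]; db <- l$g[[gb]]
    dhnext <- matrix(0, f, B)
    n <- length(ts)
    for (i in n:1) {
      t <- ts[i]
      h <- xa_t(hs, t)
      dh <- xa_t(dya, t)[dslice, , drop = FALSE] + dhnext
      dt <- dh * (1 - h * h)
      hp <- if (i > 1) xa_t(hs, ts[i - 1]) else matrix(0, f, B)
      dwx <- dwx + dt %*% t(xa_t(cache$xa, t))
      dwh <- dwh + dt %*% t(hp)
      db <- db + rowSums(dt)
      dxa[, , t] <<- xa_t(dxa, t) + crossprod(wx, dt)
      dhnext <- crossprod(wh, dt)
    }
    l$g[[gw]] <- dwx; l$g[[gh]] <- dwh; l$g[[gb]] <- db
  }
  bptt(cache$hs1, l$p$wx1, l$p$wh1, seq_len(TT), seq_len(f),
       "wx1", "wh1", "b1")
  bptt(cache$hs2, l$p$wx2, l$p$wh2, rev(seq_len(TT)), f + seq_len(f),
       "wx2", "wh2", "b2")
  dxp <- array(dxa, c(C, d[pm[2]], d[pm[3]], TT))
  aperm(dxp, order(pm))
}

xa_t <- function(xa, t) {
  m <- xa[, , t, drop = FALSE]
  dim(m) <- dim(xa)[1:2]
  m
}

# ---------------------------------------------------------------------------
# squeeze-and-excitation blocks

cse_forward <- function(l, x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  z <- matrix(colMeans(matrix(x, hw, d[3] * d[4])), d[3], d[4])
  a1lin <- sweep(l$p$w1 %*% z, 1, l$p$b1, "+")
  a1 <- a1lin * (a1lin > 0)
  s <- sigmoid(sweep(l$p$w2 %*% a1, 1, l$p$b2, "+"))
  sf <- array(rep(s, each = hw), d)
  list(y = x * sf,
       cache = list(x = x, z = z, a1 = a1, mask1 = a1lin > 0, s = s, sf = sf))
}

cse_backward <- function(l, dy, cache) {
  d <- dim(dy)
  hw <- d[1] * d[2]
  ds <- matrix(colSums(matrix(dy * cache$x, hw, d[3] * d[4])), d[3], d[4])
  dlin2 <- ds * cache$s * (1 - cache$s)
  l$g$w2 <- l$g$w2 + dlin2 %*% t(cache$a1)
  l$g$b2 <- l$g$b2 + rowSums(dlin2)
  da1 <- (t(l$p$w2) %*% dlin2) * cache$mask1
  l$g$w1 <- l$g$w1 + da1 %*% t(cache$z)
  l$g$b1 <- l$g$b1 + rowSums(da1)
  dz <- t(l$p$w1) %*% da1
  dy * cache$sf + array(rep(dz / hw, each = hw), d)
}

sse_forward <- function(l, x) {
  d <- dim(x)
  xp <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])     # (H*W*N) x C
  qlin <- drop(xp %*% l$p$w) + l$p$b
  q <- sigmoid(qlin)                                      # length H*W*N
  qf <- aperm(array(q, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(y = x * qf, cache = list(x = x, xp = xp, q = q, qf = qf))
}

sse_backward <- function(l, dy, cache) {
  d <- dim(dy)
  dyp <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = d[3])
  dq <- rowSums(dyp * cache$xp)
  dqlin <- dq * cache$q * (1 - cache$q)
  l$g$w <- l$g$w + drop(crossprod(cache$xp, dqlin))
  l$g$b <- l$g$b + sum(dqlin)
  dxp <- outer(dqlin, l$p$w)
  dxadd <- aperm(array(dxp, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  dy * cache$qf + dxadd
}

scse_forward <- function(l, x, train) {
  rc <- ly_forward(l$children$cse, x, train)
  rs <- ly_forward(l$children$sse, x, train)
  if (l$s$combine == "add") {
    list(y = rc$y + rs$y, cache = list(cc = rc$cache, cs = rs$cache,
                                       mask = NULL))
  } else {
    mask <- rc$y >= rs$y
    list(y = pmax(rc$y, rs$y),
         cache = list(cc = rc$cache, cs = rs$cache, mask = mask))
  }
}

scse_backward <- function(l, dy, cache) {
  if (is.null(cache$mask)) {
    ly_backward(l$children$cse, dy, cache$cc) +
      ly_backward(l$children$sse, dy, cache$cs)
  } else {
    ly_backward(l$children$cse, dy * cache$mask, cache$cc) +
      ly_backward(l$children$sse, dy * !cache$mask, cache$cs)
  }
}

# ---------------------------------------------------------------------------
# convolution block (optionally residual, optionally SE)

block_forward <- function(l, x, train) {
  ch <- l$children
  r1 <- ly_forward(ch$conv1, x, train)
  r2 <- ly_forward(ch$bn1, r1$y, train)
  m1 <- r2$y > 0
  a1 <- r2$y * m1
  r3 <- ly_forward(ch$conv2, a1, train)
  r4 <- ly_forward(ch$bn2, r3$y, train)
  caches <- list(c1 = r1$cache, b1 = r2$cache, m1 = m1, c2 = r3$cache,
                 b2 = r4$cache)
  pre <- r4$y
  if (l$s$residual) {
    if (!is.null(ch$proj)) {
      rp <- ly_forward(ch$proj, x, train)
      caches$proj <- rp$cache
      pre <- pre + rp$y
    } else pre <- pre + x
  }
  m2 <- pre > 0
  y <- pre * m2
  caches$m2 <- m2
  if (!is.null(ch$se)) {
    rs <- ly_forward(ch$se, y, train)
    caches$se <- rs$cache
    y <- rs$y
  }
  list(y = y, cache = caches)
}

block_backward <- function(l, dy, cache) {
  ch <- l$children
  if (!is.null(ch$se)) dy <- ly_backward(ch$se, dy, cache$se)
  dpre <- dy * cache$m2
  dx_res <- NULL
  if (l$s$residual) {
    dx_res <- if (!is.null(ch$proj))
      ly_backward(ch$proj, dpre, cache$proj) else dpre
  }
  d4 <- ly_backward(ch$bn2, dpre, cache$b2)
  d3 <- ly_backward(ch$conv2, d4, cache$c2)
  d3 <- d3 * cache$m1
  d2 <- ly_backward(ch$bn1, d3, cache$b1)
  d1 <- ly_backward(ch$conv1, d2, cache$c1)
  if (!is.null(dx_res)) d1 <- d1 + dx_res
  d1
}

# ---------------------------------------------------------------------------
# sequential container helpers

seq_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- ly_forward(layers[[i]], x, train)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

seq_backward <- function(layers, dy, caches) {
  for (i in rev(seq_along(layers)))
    dy <- ly_backward(layers[[i]], dy, caches[[i]])
  dy
}

# all primitive (parameter-bearing) layers, recursing into composites
collect_layers <- function(x) {
  if (inherits(x, "octseg_layer")) {
    c(list(x), collect_layers(x$children))
  } else if (is.list(x)) {
    unlist(lapply(x, collect_layers), recursive = FALSE)
  } else list()
}

count_params <- function(layers) {
  sum(vapply(collect_layers(layers),
             function(l) sum(vapply(l$p, length, 0L)), 0))
}

zero_grads <- function(layers) {
  for (l in collect_layers(layers))
    l$g <- lapply(l$p, function(a) array(0, dim(a) %||% length(a)))
  invisible(NULL)
}

# deep copy / restore of parameters and BN running stats (for checkpointing
# the best-validation epoch)
snapshot_params <- function(layers) {
  lapply(collect_layers(layers), function(l) list(p = l$p, s = l$s))
}

restore_params <- function(layers, snap) {
  ls <- collect_layers(layers)
  stopifnot(length(ls) == length(snap))
  for (i in seq_along(ls)) {
    ls[[i]]$p <- snap[[i]]$p
    ls[[i]]$s <- snap[[i]]$s
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Adam optimiser (alpha = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)

adam_new <- function(layers, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$layers <- collect_layers(layers)
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  for (l in opt$layers) {
    l$m <- lapply(l$p, function(a) array(0, dim(a) %||% length(a)))
    l$v <- lapply(l$p, function(a) array(0, dim(a) %||% length(a)))
  }
  opt
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (l in opt$layers) {
    for (k in names(l$p)) {
      g <- l$g[[k]]
      l$m[[k]] <- b1 * l$m[[k]] + (1 - b1) * g
      l$v[[k]] <- b2 * l$v[[k]] + (1 - b2) * g * g
      l$p[[k]] <- l$p[[k]] - opt$lr * (l$m[[k]] / corr1) /
        (sqrt(l$v[[k]] / corr2) + opt$eps)
    }
    l$g <- lapply(l$g, function(a) a * 0)
  }
  invisible(NULL)
}
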