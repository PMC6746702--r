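# The training engine is exercised through numeric gradient checks (central
# differences against hand-written backprop) and the architectural contracts
# of the patch and semantic builders.

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
`%||%` <- octseg:::`%||%`

rel_err <- function(a, b) max(abs(a - b)) / max(1, max(abs(b)))

test_that("layer backprop matches numeric gradients", {
  ns <- asNamespace("octseg")
  set.seed(42)
  cases <- list(
    conv = list(make = function() ns$nn_conv(3, 3, 2, 3), dim = c(5, 6, 2, 2)),
    bn = list(make = function() ns$nn_bn(3), dim = c(4, 5, 3, 2)),
    pool = list(make = function() ns$nn_pool(), dim = c(4, 6, 2, 2)),
    up = list(make = function() ns$nn_up(), dim = c(3, 4, 2, 2)),
    rnn_v = list(make = function() ns$nn_rnn("v", 2, 3), dim = c(4, 5, 2, 2)),
    rnn_h = list(make = function() ns$nn_rnn("h", 2, 3), dim = c(4, 5, 2, 2)),
    cse = list(make = function() ns$nn_cse(4), dim = c(3, 4, 4, 2)),
    sse = list(make = function() ns$nn_sse(3), dim = c(3, 4, 3, 2)),
    block = list(make = function() ns$nn_block(2, 3, residual = TRUE,
                                               se = "scse"),
                 dim = c(4, 6, 2, 2)))
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    l <- cs$make()
    x <- array(rnorm(prod(cs$dim)), cs$dim)
    r0 <- ns$ly_forward(l, x, TRUE)
    r <- array(rnorm(length(r0$y)), dim(r0$y))
    ns$zero_grads(l)
    dx <- ns$ly_backward(l, r, r0$cache)
    gx <- num_grad(function(xx) sum(ns$ly_forward(l, xx, TRUE)$y * r), x)
    expect_lt(rel_err(dx, gx), 1e-6)
    for (k in names(l$p)) {
      p0 <- l$p[[k]]
      f <- function(pp) {
        l$p[[k]] <- pp
        out <- sum(ns$ly_forward(l, x, TRUE)$y * r)
        l$p[[k]] <- p0
        out
      }
      expect_lt(rel_err(l$g[[k]], num_grad(f, p0)), 1e-6)
    }
  }
})

test_that("semantic network end-to-end gradient matches numeric gradient", {
  ns <- asNamespace("octseg")
  set.seed(11)
  net <- build_semantic_model("combined", base_filters = 2, n_pool = 2)
  x <- array(runif(8 * 12), c(8, 12, 1, 1))
  g <- ns$one_hot_mask(matrix(sample(0:3, 8 * 12, TRUE), 8, 12))
  r <- ns$semantic_net_forward(net, x, FALSE)
  lo <- ns$semantic_loss(r$y, g)
  ns$zero_grads(net)
  dx <- ns$semantic_net_backward(net, lo$dz, r$caches)
  gx <- num_grad(function(xx) {
    rr <- ns$semantic_net_forward(net, xx, FALSE)
    ns$semantic_loss(rr$y, g)$loss
  }, x)
  expect_lt(max(abs(dx - gx)) / max(1e-3, max(abs(gx))), 1e-5)
})

test_that("patch networks output normalised 4-way probabilities", {
  set.seed(3)
  for (a in c("cifar_cnn", "complex_cnn", "renet_rnn")) {
    net <- build_patch_model(a, patch_spec(32, 32))
    p <- patch_net_predict(net, array(runif(32 * 32 * 5), c(32, 32, 1, 5)))
    expect_equal(dim(p), c(4, 5))
    expect_equal(colSums(p), rep(1, 5), tolerance = 1e-6)
  }
  expect_error(build_patch_model("cifar_cnn", patch_spec(34, 34)),
               "divisible")
})

test_that("the recurrent patch network has the fewest parameters", {
  set.seed(3)
  n_rnn <- n_parameters(build_patch_model("renet_rnn", patch_spec(32, 32)))
  n_cifar <- n_parameters(build_patch_model("cifar_cnn", patch_spec(32, 32)))
  n_complex <- n_parameters(build_patch_model("complex_cnn",
                                              patch_spec(32, 32)))
  expect_lt(n_rnn, n_complex)
  expect_lt(n_rnn, n_cifar)
  expect_lt(n_cifar, n_complex)
})

test_that("model builds are deterministic given the seed", {
  set.seed(5); m1 <- build_patch_model("cifar_cnn", patch_spec(32, 32))
  set.seed(5); m2 <- build_patch_model("cifar_cnn", patch_spec(32, 32))
  expect_identical(m1$layers[[1]]$p$w, m2$layers[[1]]$p$w)
  set.seed(5); s1 <- build_semantic_model("standard")
  set.seed(5); s2 <- build_semantic_model("standard")
  expect_identical(s1$enc[[1]]$children$conv1$p$w,
                   s2$enc[[1]]$children$conv1$p$w)
})

test_that("semantic builder follows the filter-doubling progression", {
  net <- build_semantic_model("standard", base_filters = 8, n_pool = 4)
  expect_equal(net$filters, c(8, 16, 32, 64, 128))
  enc_out <- vapply(net$enc, function(b) dim(b$children$conv2$p$w)[4], 0)
  expect_equal(enc_out, c(8, 16, 32, 64))
  expect_equal(dim(net$bottleneck$block$children$conv2$p$w)[4], 128)
  # output contract: H x W x 4 per-pixel probabilities summing to 1
  ns <- asNamespace("octseg")
  set.seed(1)
  net2 <- build_semantic_model("standard", base_filters = 2, n_pool = 2)
  probs <- semantic_net_predict(net2, matrix(runif(16 * 20, 0, 255), 16, 20))
  expect_equal(dim(probs), c(16, 20, 4))
  expect_equal(apply(probs, c(1, 2), sum),
               matrix(1, 16, 20), tolerance = 1e-9)
  expect_error(ns$semantic_net_forward(net2, array(0, c(10, 20, 1, 1))),
               "divisible")
})

test_that("scSE output equals the element-wise max of cSE and sSE", {
  ns <- asNamespace("octseg")
  set.seed(8)
  l <- ns$nn_scse(6)
  x <- array(runif(4 * 5 * 6 * 2), c(4, 5, 6, 2))
  y <- ns$ly_forward(l, x, FALSE)$y
  yc <- ns$ly_forward(l$children$cse, x, FALSE)$y
  ys <- ns$ly_forward(l$children$sse, x, FALSE)$y
  expect_identical(y, pmax(yc, ys))
})

test_that("dice loss matches hand-computed values and symmetries", {
  ns <- asNamespace("octseg")
  # uniform prediction, balanced classes, s -> 0: per class
  # 2 * (N/16) / (N/16 + N/4) = 0.4, loss = 0.6
  gt <- ns$one_hot_mask(matrix(rep(0:3, each = 4), 4, 4))
  unif <- array(0.25, c(4, 4, 4, 1))
  expect_equal(dice_overlap_loss(unif, gt, smooth = 1e-12), 0.6,
               tolerance = 1e-9)
  expect_equal(dice_overlap_loss(gt, gt, smooth = 1e-12), 0,
               tolerance = 1e-9)
  expect_gte(dice_overlap_loss(unif, gt), 0)
  # invariant to flipping prediction and target together
  set.seed(2)
  p <- array(runif(4 * 6 * 4), c(4, 6, 4, 1))
  g <- ns$one_hot_mask(matrix(sample(0:3, 24, TRUE), 4, 6))
  fl <- function(a) a[, 6:1, , , drop = FALSE]
  expect_equal(dice_overlap_loss(p, g), dice_overlap_loss(fl(p), fl(g)))
  expect_error(dice_overlap_loss(p, g[, 1:3, , , drop = FALSE]), "differ")
})

test_that("a linearly separable patch problem reaches perfect accuracy", {
  # bright vs dark patches, collapsed into 2 of the 4 classes
  set.seed(21)
  n <- 80
  x <- array(0, c(16, 16, 1, n))
  y <- rep(c(1L, 4L), n / 2)
  for (i in seq_len(n))
    x[, , 1, i] <- (if (y[i] == 1L) 0.8 else 0.2) + rnorm(256, 0, 0.05)
  ns <- asNamespace("octseg")
  net <- build_patch_model("cifar_cnn", patch_spec(16, 16))
  opt <- ns$adam_new(net$layers)
  acc <- 0
  for (ep in 1:20) {
    ord <- sample.int(n)
    for (s in seq(1, n, 16)) {
      idx <- ord[s:min(s + 15, n)]
      r <- ns$patch_net_forward(net, x[, , , idx, drop = FALSE], TRUE)
      lo <- ns$patch_loss(r$y, y[idx])
      ns$seq_backward(net$layers, lo$dz, r$caches)
      ns$adam_step(opt)
    }
    p <- patch_net_predict(net, x)
    acc <- mean(apply(p, 2, which.max) == y)
    if (acc == 1) break
  }
  expect_equal(acc, 1)
})

test_that("checkpoint selection returns the argmax-validation epoch", {
  # tiny dataset, few epochs: the reported best epoch must attain the
  # maximum of the validation metric column of the log
  fx1 <- flat_fixture(seed = 31, size = 32)
  fx2 <- flat_fixture(seed = 32, size = 32)
  ds <- as_dataset(list(fixture_entry(fx1, 1, "a")),
                   list(fixture_entry(fx2, 2, "b")))
  m <- fit_semantic_segmenter(ds, "standard", epochs = 4, batch_size = 1,
                              base_filters = 2, n_pool = 2, seed = 2)
  expect_equal(nrow(m$log), 4)
  expect_equal(m$log$epoch, 1:4)
  expect_equal(m$log$val_metric[m$best_epoch], max(m$log$val_metric))
  expect_true(all(is.finite(m$log$train_loss)))
})

test_that("a small noise-free cohort is fit to high validation Dice", {
  entries <- lapply(1:8, function(i) {
    pp <- phantom_params_scaled(64, 64, speckle_level = 0,
                                shadow_count = 0L, missing_margin = 0L,
                                seed = 100L + i)
    b <- generate_boundaries(pp)
    list(scan = render_bscan(pp, b, paste0("e", i)), boundaries = b,
         participant = i, id = paste0("e", i))
  })
  ds <- as_dataset(entries[1:6], entries[7:8])
  m <- fit_semantic_segmenter(ds, "standard", epochs = 30, batch_size = 2,
                              seed = 4)
  expect_gt(max(m$log$val_metric), 95)
})
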