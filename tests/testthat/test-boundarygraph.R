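test_that("edge weights match closed-form substitution", {
  expect_equal(edge_weight(1, 1), 0.00001)
  expect_equal(edge_weight(0, 0), 2.00001)
  expect_equal(edge_weight(0.5, 0.25), 1.25001)
  grid <- expand.grid(ps = seq(0, 1, 0.25), pd = seq(0, 1, 0.25))
  expect_equal(edge_weight(grid$ps, grid$pd),
               2 - (grid$ps + grid$pd) + 1e-5)
  expect_true(all(edge_weight(grid$ps, grid$pd) > 0))
  expect_error(edge_weight(1.2, 0), "\\[0, 1\\]")
  expect_error(edge_weight(0.5, -0.1), "\\[0, 1\\]")
})

test_that("graph search equals the DP oracle on random maps", {
  set.seed(99)
  for (i in 1:100) {
    P <- matrix(runif(8 * 8), 8, 8)
    got <- shortest_path_boundary(P)
    ora <- dp_boundary_oracle(P)
    expect_identical(as.integer(got), as.integer(ora$rows))
    expect_equal(path_cost(P, got), ora$cost, tolerance = 1e-10)
  }
})

test_that("ideal staircase maps are recovered exactly", {
  set.seed(123)
  for (i in 1:50) {
    h <- sample(6:12, 1); w <- sample(6:15, 1)
    truth <- integer(w)
    truth[1] <- sample(0:(h - 1), 1)
    for (cc in 2:w)
      truth[cc] <- min(h - 1, max(0, truth[cc - 1] + sample(-1:1, 1)))
    P <- matrix(0, h, w)
    P[cbind(truth + 1, 1:w)] <- 1
    expect_identical(as.integer(shortest_path_boundary(P)),
                     as.integer(truth))
  }
})

test_that("single probability-1 row gives a constant path", {
  P <- matrix(0, 9, 12)
  P[5, ] <- 1
  expect_equal(shortest_path_boundary(P), rep(4L, 12))
})

test_that("returned paths satisfy the structural invariants", {
  set.seed(4)
  for (i in 1:20) {
    P <- matrix(runif(10 * 10), 10, 10)
    rows <- shortest_path_boundary(P)
    expect_length(rows, 10)                        # real columns only
    expect_true(all(rows >= 0 & rows <= 9))
    expect_lte(max(abs(diff(rows))), 1)            # column-monotone moves
  }
  expect_error(shortest_path_boundary(matrix(0.5, 4, 1)), "2 columns")
  expect_error(shortest_path_boundary(matrix(2, 4, 4)), "\\[0, 1\\]")
})

test_that("raising a probability on the path never increases its cost", {
  set.seed(14)
  for (i in 1:10) {
    P <- matrix(runif(8 * 8, 0, 0.9), 8, 8)
    rows <- shortest_path_boundary(P)
    c0 <- path_cost(P, rows)
    cc <- sample(8, 1)
    P2 <- P
    P2[rows[cc] + 1, cc] <- P[rows[cc] + 1, cc] + 0.1
    rows2 <- shortest_path_boundary(P2)
    expect_lte(path_cost(P2, rows2), c0 + 1e-12)
  }
})

test_that("sobel conversion matches a hand-computed oracle", {
  set.seed(6)
  plane <- matrix(runif(36), 6, 6)
  got <- octseg:::sobel_vertical(plane)
  expect_equal(got, sobel_oracle(plane))
})

test_that("boundary maps respond to region steps and ignore flat fields", {
  # hard step in the retina plane between rows 3 and 4 (0-based) -> the ILM
  # map peaks at the step and is zero far away
  probs <- array(0, c(10, 8, 4))
  probs[1:4, , 1] <- 1     # vitreous rows 0..3
  probs[5:10, , 2] <- 1    # retina rows 4..9
  probs[, , 3] <- 0; probs[, , 4] <- 0
  maps <- semantic_boundary_maps(probs)
  expect_equal(which.max(maps$ilm[, 4]) - 1L, 4L)
  expect_equal(max(maps$ilm), 1)
  expect_equal(maps$ilm[8:10, ], matrix(0, 3, 8))
  # uniform probabilities -> all-zero maps
  unif <- array(0.25, c(6, 6, 4))
  m0 <- semantic_boundary_maps(unif)
  expect_true(all(vapply(m0, function(m) all(m == 0), TRUE)))
})

test_that("lower alignment puts the peak on the lower step pixel", {
  # step from 0 to 1 between rows r-1 = 4 and r = 5 in the sclera plane
  probs <- array(0, c(12, 6, 4))
  probs[1:5, , 3] <- 1
  probs[6:12, , 4] <- 1
  probs[, , 1] <- 0; probs[, , 2] <- 0
  centered <- semantic_boundary_maps(probs, align = "centered")$csi
  lower <- semantic_boundary_maps(probs, align = "lower")$csi
  # the raw Sobel response plateaus over both step rows ...
  expect_equal(centered[5, 3], centered[6, 3])
  # ... while the lower alignment has its unique maximum on row 5 (0-based)
  expect_equal(which.max(lower[, 3]) - 1L, 5L)
  expect_gt(lower[6, 3], lower[7, 3])
})

test_that("a one-hot background patch model yields all-zero boundary maps", {
  fx <- flat_fixture(size = 32)
  net <- build_patch_model("cifar_cnn", patch_spec(8, 8))
  # force the final layer to emit background with overwhelming logit
  fc <- net$layers[[length(net$layers)]]
  fc$p$w[] <- 0
  fc$p$b <- c(-50, -50, -50, 50)
  maps <- patch_probability_maps(net, fx$scan, crop_region(2, 2))
  for (k in 1:3) expect_lt(max(maps[[k]]), 1e-6)
  # per-pixel probabilities over the 4 classes still sum to 1
  p <- patch_net_predict(net, array(runif(8 * 8), c(8, 8, 1, 1)))
  expect_equal(sum(p), 1, tolerance = 1e-9)
})

test_that("segmentation output is deterministic and column-smooth", {
  fx <- flat_fixture(size = 32)
  set.seed(2)
  net <- build_patch_model("cifar_cnn", patch_spec(8, 8))
  maps <- patch_probability_maps(net, fx$scan, crop_region(2, 2))
  b1 <- octseg:::maps_to_boundaries(maps)
  b2 <- octseg:::maps_to_boundaries(maps)
  expect_identical(b1$ilm, b2$ilm)
  for (k in c("ilm", "rpe", "csi"))
    expect_lte(max(abs(diff(b1[[k]]))), 1)
})
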