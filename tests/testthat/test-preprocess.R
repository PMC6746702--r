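test_that("attenuation compensation matches the closed forms", {
  eps <- 1e-6
  # single-pixel column: v^n / (2 v^n + eps) ~ 0.5 before rescaling
  raw1 <- octseg:::attenuation_compensate_raw(matrix(100), exponent = 2,
                                              floor = eps)
  expect_equal(raw1[1, 1], 100^2 / (2 * 100^2 + eps))
  expect_lt(abs(raw1[1, 1] - 0.5), 1e-6)
  # two-pixel column, n = 1: (a/(2(a+b)+eps), b/(2b+eps))
  a <- 37; b <- 112
  raw2 <- octseg:::attenuation_compensate_raw(matrix(c(a, b), 2, 1),
                                              exponent = 1, floor = eps)
  expect_equal(raw2[, 1], c(a / (2 * (a + b) + eps), b / (2 * b + eps)))
})

test_that("enhanced output is finite, non-negative and in range", {
  fx <- curved_fixture()
  for (n in c(1, 2)) {
    e <- contrast_enhance(fx$scan, exponent = n)
    expect_true(all(is.finite(e$pixels)))
    expect_gte(min(e$pixels), 0)
    expect_lte(max(e$pixels), 255)
  }
  # all-zero columns stay zero
  z <- bscan(matrix(0, 8, 4))
  expect_equal(contrast_enhance(z)$pixels, matrix(0, 8, 4))
})

test_that("enhancement raises the choroid/sclera contrast at the CSI", {
  pp <- phantom_params(width = 64, height = 96,
                       mean_depths = c(15, 35, 60),
                       curvature_amplitude = 0, speckle_level = 0,
                       attenuation_rate = 0.004, shadow_count = 0,
                       missing_margin = 0)
  b <- generate_boundaries(pp)
  scan <- render_bscan(pp, b)
  enh <- contrast_enhance(scan)
  # Michelson contrast between the mean choroid and sclera band intensities
  contrast <- function(px) {
    a <- mean(px[36:60, ]); s <- mean(px[61:96, ])
    abs(a - s) / (a + s)
  }
  expect_gt(contrast(enh$pixels), contrast(scan$pixels))
})

test_that("area mask follows the region convention and inverts", {
  b <- boundary_set(rep(10, 6), rep(20, 6), rep(30, 6))
  m <- boundaries_to_area_mask(b, 40, 6)
  expect_equal(as.vector(table(m[, 1])), c(10, 10, 10, 10))
  # monotone labels per column
  expect_true(all(apply(m, 2, function(col) all(diff(col) >= 0))))
  # inverse scan recovers the integer boundaries
  back <- area_mask_to_boundaries(m)
  expect_equal(back$ilm, rep(10, 6))
  expect_equal(back$rpe, rep(20, 6))
  expect_equal(back$csi, rep(30, 6))
})

test_that("columns with a missing boundary are labelled all vitreous", {
  b <- boundary_set(c(10, 10, 10), c(20, 20, 20), c(30, NA, 30))
  m <- boundaries_to_area_mask(b, 40, 3)
  expect_equal(m[, 2], rep(0L, 40))
  expect_equal(m[10:11, 1], c(0L, 1L))
})

test_that("fractional boundary rows are rounded half-up", {
  b <- boundary_set(c(10.5, 10.49), c(20.5, 20.5), c(30, 30))
  m <- boundaries_to_area_mask(b, 40, 2)
  back <- area_mask_to_boundaries(m)
  expect_equal(back$ilm, c(11, 10))
  expect_equal(back$rpe, c(21, 21))
})

test_that("zeroing missing columns removes exactly their mass", {
  fx <- curved_fixture()
  b <- fx$boundaries
  miss <- c(2, 9, 17, 40, 63)
  b$csi[miss] <- NA
  z <- zero_missing_columns(fx$scan, b)
  expect_equal(sum(z$pixels[, miss]), 0)
  expect_identical(z$pixels[, -miss], fx$scan$pixels[, -miss])
  expect_equal(sum(fx$scan$pixels) - sum(z$pixels),
               sum(fx$scan$pixels[, miss]))
  # no missing columns: identity
  expect_identical(zero_missing_columns(fx$scan, fx$boundaries)$pixels,
                   fx$scan$pixels)
})

test_that("horizontal flip is a consistent involution", {
  fx <- flat_fixture()
  m <- boundaries_to_area_mask(fx$boundaries, 64, 64)
  f1 <- random_horizontal_flip(fx$scan$pixels, m, probability = 1)
  expect_true(f1$flipped)
  expect_equal(f1$pixels[, 64], fx$scan$pixels[, 1])
  expect_equal(f1$mask[, 1], m[, 64])
  # monotone labels preserved
  expect_true(all(apply(f1$mask, 2, function(col) all(diff(col) >= 0))))
  f2 <- random_horizontal_flip(f1$pixels, f1$mask, probability = 1)
  expect_identical(f2$pixels, fx$scan$pixels)
  expect_identical(f2$mask, m)
  expect_error(random_horizontal_flip(fx$scan$pixels, m[, 1:10]),
               "shapes differ")
})

test_that("flip frequency over 10,000 seeded draws is near one half", {
  px <- matrix(0, 2, 2); mk <- matrix(0L, 2, 2)
  set.seed(77)
  flips <- vapply(1:10000, function(i)
    random_horizontal_flip(px, mk)$flipped, TRUE)
  expect_lt(abs(mean(flips) - 0.5), 0.02)
})
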