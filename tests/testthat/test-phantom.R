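test_that("zero curvature gives constant boundaries at the mean depths", {
  pp <- phantom_params(width = 64, height = 256,
                       mean_depths = c(50, 120, 200),
                       curvature_amplitude = 0, missing_margin = 0)
  b <- generate_boundaries(pp)
  expect_equal(b$ilm, rep(50, 64))
  expect_equal(b$rpe, rep(120, 64))
  expect_equal(b$csi, rep(200, 64))
})

test_that("boundary generation is deterministic given the seed", {
  pp <- phantom_params(width = 128, height = 256,
                       mean_depths = c(50, 120, 200), seed = 42)
  b1 <- generate_boundaries(pp)
  b2 <- generate_boundaries(pp)
  expect_identical(b1, b2)
  s1 <- render_bscan(pp, b1)
  s2 <- render_bscan(pp, b2)
  expect_identical(s1$pixels, s2$pixels)
})

test_that("boundary ordering holds at every annotated column", {
  for (seed in 1:5) {
    pp <- phantom_params(width = 200, height = 256,
                         mean_depths = c(50, 120, 200),
                         curvature_amplitude = 30, seed = seed)
    b <- generate_boundaries(pp)
    cols <- which(!is.na(b$ilm))
    expect_true(all(b$rpe[cols] - b$ilm[cols] > 0))
    expect_true(all(b$csi[cols] - b$rpe[cols] > 0))
    expect_true(all(b$ilm[cols] >= 0 & b$csi[cols] <= 255))
  }
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_params(mean_depths = c(120, 100, 200)),
               "strictly increasing")
  expect_error(phantom_params(mean_depths = c(120, 200, 600)),
               "inside")
  expect_error(phantom_params(speckle_level = -1))
  expect_error(phantom_params(shadow_attenuation = 2))
})

test_that("noise-free rendering is piecewise constant at the boundary rows", {
  pp <- phantom_params(width = 32, height = 64,
                       mean_depths = c(10, 25, 40),
                       curvature_amplitude = 0, speckle_level = 0,
                       attenuation_rate = 0, shadow_count = 0,
                       missing_margin = 0)
  b <- generate_boundaries(pp)
  scan <- render_bscan(pp, b)
  col <- scan$pixels[, 7]
  ri <- pp$region_intensities
  expect_equal(col, rep(ri, times = c(10, 15, 15, 24)))
})

test_that("unit shadow attenuation leaves the image unchanged", {
  pp1 <- phantom_params(width = 64, height = 64,
                        mean_depths = c(10, 25, 40), shadow_count = 3,
                        shadow_attenuation = 1, missing_margin = 0,
                        seed = 9)
  pp0 <- pp1; pp0$shadow_count <- 0L
  b <- generate_boundaries(pp1)
  expect_identical(render_bscan(pp1, b)$pixels, render_bscan(pp0, b)$pixels)
})

test_that("mean choroid intensity matches the closed-form attenuated mean", {
  # Monte-Carlo over 20 seeds against intensity * mean row attenuation
  means <- vapply(1:20, function(seed) {
    pp <- phantom_params(width = 64, height = 96,
                         mean_depths = c(15, 35, 60),
                         curvature_amplitude = 0, speckle_level = 0.3,
                         attenuation_rate = 0.004, shadow_count = 0,
                         missing_margin = 0, seed = seed)
    b <- generate_boundaries(pp)
    scan <- render_bscan(pp, b)
    mean(scan$pixels[36:60, ])   # choroid band, rows 35..59 0-based
  }, 0)
  expected <- 90 * mean(exp(-0.004 * (35:59)))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - expected), 3 * se + 1e-9)
})

test_that("dataset split is participant-disjoint with the study counts", {
  pp <- phantom_params_scaled(48, 32, seed = 2)
  ds <- generate_dataset(50, 6, 0.8, pp)
  expect_length(ds$train, 240)
  expect_length(ds$validation, 60)
  pids_tr <- unique(vapply(ds$train, `[[`, 0, "participant"))
  pids_va <- unique(vapply(ds$validation, `[[`, 0, "participant"))
  expect_length(intersect(pids_tr, pids_va), 0)
  expect_length(pids_tr, 40)
  expect_length(pids_va, 10)

  ev <- generate_dataset(49, 6, NULL, pp)
  expect_length(ev$evaluation, 294)

  ds2 <- generate_dataset(2, 3, 0.5, pp)
  expect_length(ds2$train, 3)
  expect_length(ds2$validation, 3)
})

test_that("degenerate dataset requests error", {
  pp <- phantom_params_scaled(48, 32)
  expect_error(generate_dataset(1, 2, 0.5, pp), "participants")
  expect_error(generate_dataset(4, 2, 1.5, pp), "split_fraction")
})
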