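test_that("disc rasterization follows the pixel-centre inclusion convention", {
  # single-pixel disc centred exactly on a pixel centre
  m <- render_disc_mask(1, c(3, 3), c(7, 7))
  expect_equal(sum(m), 1)
  expect_true(m[4, 4])

  # disc larger than the grid diagonal saturates every pixel (clipped)
  m <- render_disc_mask(200, c(31.5, 31.5), c(64, 64), clip = TRUE)
  expect_true(all(m))

  # area equals brute-force enumeration of pixel centres
  for (d in c(3, 6, 9.5)) {
    ctr <- c(32, 30.25)
    area <- sum(render_disc_mask(d, ctr, c(64, 64)))
    expect_identical(area, brute_force_disc_area(d, ctr, c(64, 64)))
  }
  expect_lt(abs(sum(render_disc_mask(6, c(32, 32), c(64, 64))) - pi * 9), 4)

  # a disc poking out of the grid is rejected unless clipping is requested
  expect_error(render_disc_mask(10, c(2, 32), c(64, 64)), "extends beyond")
})

test_that("simulated stacks have Poisson statistics about the configured means", {
  cfg <- sim_config(n_frames = 2000, rows = 12, cols = 12, N0 = 80, C = 0.2,
                    detail_diameter_px = 4, frame_rate_fp = 15, seed = 11)
  pair <- simulate_stack(cfg)
  bg <- pair$background_stack$pixels
  pix_mean <- apply(bg, c(1, 2), mean)
  # ensemble background mean converges to N0 (3 SE bound, SE = sqrt(N0/n))
  se <- sqrt(cfg$N0 / cfg$n_frames)
  expect_lt(abs(mean(pix_mean) - cfg$N0), 3 * se / sqrt(length(pix_mean)) * 4)
  # Poisson identity: per-pixel variance tracks the mean within 5%
  pix_var <- apply(bg, c(1, 2), var)
  expect_lt(abs(mean(pix_var) / mean(pix_mean) - 1), 0.05)
  # signal stack mean is raised by N0*C inside the disc
  mask <- render_disc_mask(4, cfg$center, c(12, 12))
  sig_mean <- apply(pair$signal_stack$pixels, c(1, 2), mean)
  expect_lt(abs(mean(sig_mean[mask]) - cfg$N0 * 1.2), 4 * se)
})

test_that("null-contrast stacks are statistically indistinguishable", {
  cfg <- sim_config(n_frames = 1500, rows = 10, cols = 10, N0 = 100, C = 0,
                    detail_diameter_px = 4, seed = 12)
  pair <- simulate_stack(cfg)
  d <- mean(pair$signal_stack$pixels) - mean(pair$background_stack$pixels)
  se <- sqrt(2 * cfg$N0 / (cfg$n_frames * 100))
  expect_lt(abs(d), 4 * se)
})

test_that("AR(1) noise reproduces the requested lag-1 correlation and clips negatives", {
  cfg <- sim_config(n_frames = 2000, rows = 8, cols = 8, N0 = 100, C = 0.1,
                    detail_diameter_px = 3, ar1_alpha = 0.5, seed = 13)
  pair <- simulate_stack(cfg)
  arr <- pair$background_stack$pixels
  rho1 <- mean(apply(arr, c(1, 2), function(x) {
    x <- x - mean(x)
    sum(x[-length(x)] * x[-1]) / sum(x^2)
  }))
  expect_lt(abs(rho1 - 0.5), 0.05)

  # tiny N0 forces the Gaussian branch below zero: clipped with a warning
  cfg_low <- sim_config(n_frames = 200, rows = 8, cols = 8, N0 = 2, C = 0.1,
                        detail_diameter_px = 3, ar1_alpha = 0.3, seed = 14)
  expect_warning(pair_low <- simulate_stack(cfg_low), "clipped")
  expect_gt(sum(pair_low$n_clipped), 0)
  expect_true(min(pair_low$background_stack$pixels) >= 0)
})

test_that("a fixed seed reproduces stacks bit-for-bit and restores the RNG", {
  cfg <- sim_config(n_frames = 20, rows = 6, cols = 6, N0 = 50, C = 0.1,
                    detail_diameter_px = 3, seed = 99)
  set.seed(7); before <- rnorm(1)
  a <- simulate_stack(cfg)
  b <- simulate_stack(cfg)
  expect_identical(a$signal_stack$pixels, b$signal_stack$pixels)
  expect_identical(a$background_stack$pixels, b$background_stack$pixels)
  set.seed(7); expect_identical(rnorm(1), before)
})

test_that("analytic ideal-observer oracle is A*C^2*N0 with Rose-model scaling", {
  cfg <- sim_config(n_frames = 10, rows = 41, cols = 41, N0 = 100, C = 0.1,
                    detail_diameter_px = 8, center = c(20, 20))
  a_px <- brute_force_disc_area(8, c(20, 20), c(41, 41))
  expect_equal(analytic_ideal_snr_sf(cfg), a_px * 0.1^2 * 100)

  # linearity in N0 and A, square-law symmetry in C
  cfg2 <- sim_config(n_frames = 10, rows = 41, cols = 41, N0 = 200, C = 0.1,
                     detail_diameter_px = 8, center = c(20, 20))
  expect_equal(analytic_ideal_snr_sf(cfg2), 2 * analytic_ideal_snr_sf(cfg))
  cfg_neg <- sim_config(n_frames = 10, rows = 41, cols = 41, N0 = 100,
                        C = -0.1, detail_diameter_px = 8, center = c(20, 20))
  expect_equal(analytic_ideal_snr_sf(cfg_neg), analytic_ideal_snr_sf(cfg))
  cfg0 <- sim_config(n_frames = 10, rows = 41, cols = 41, N0 = 100, C = 0,
                     detail_diameter_px = 8, center = c(20, 20))
  expect_equal(analytic_ideal_snr_sf(cfg0), 0)

  # oracle undefined once the mean image is blurred
  cfg_blur <- sim_config(n_frames = 10, rows = 41, cols = 41, N0 = 100,
                         C = 0.1, detail_diameter_px = 8, center = c(20, 20),
                         psf_sigma_px = 1)
  expect_error(analytic_ideal_snr_sf(cfg_blur), "blurred")
})

test_that("analytic AR(1) lag factor matches the effective-sample-size closed form", {
  expect_equal(analytic_lag_ar1(0, 15), 15)
  expect_equal(analytic_lag_ar1(0.5, 15), 5)      # (1-a)/(1+a) = 1/3
  expect_lt(analytic_lag_ar1(0.999, 15), 0.01)
  expect_error(analytic_lag_ar1(1, 15), "alpha")
  expect_error(analytic_lag_ar1(-0.1, 15), "alpha")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_frames = 1, N0 = 100, C = 0.1,
                          detail_diameter_px = 4), "n_frames")
  expect_error(sim_config(n_frames = 10, N0 = -1, C = 0.1,
                          detail_diameter_px = 4), "N0")
  expect_error(sim_config(n_frames = 10, N0 = 100, C = 1.2,
                          detail_diameter_px = 4), "C")
  expect_error(sim_config(n_frames = 10, N0 = 100, C = 0.1,
                          detail_diameter_px = 4, ar1_alpha = 1), "ar1_alpha")
  # detail must fit inside the grid
  expect_error(sim_config(n_frames = 10, rows = 16, cols = 16, N0 = 100,
                          C = 0.1, detail_diameter_px = 40), "extends beyond")
})

test_that("blur moves signal energy out of the disc but preserves the total", {
  cfg <- sim_config(n_frames = 50, rows = 32, cols = 32, N0 = 400, C = 0.2,
                    detail_diameter_px = 6, psf_sigma_px = 1.5, seed = 15)
  pair <- simulate_stack(cfg)
  mask <- render_disc_mask(6, cfg$center, c(32, 32))
  mean_img <- apply(pair$signal_stack$pixels, c(1, 2), mean)
  excess <- mean_img - cfg$N0
  # blur conserves the integrated contrast but spreads it beyond the disc
  expect_lt(abs(sum(excess) / (cfg$N0 * cfg$C * sum(mask)) - 1), 0.05)
  expect_lt(max(excess), cfg$N0 * cfg$C)
})
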