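test_that("ROI extraction preserves frames and rejects out-of-bounds specs", {
  stack <- toy_stack(3, rows = 96, cols = 96)
  # whole-frame ROI is the identity
  whole <- extract_roi(stack, roi_spec(0, 0, 96, 96))
  expect_identical(whole$pixels, stack$pixels)
  # the conventional 64x64 analysis ROI
  sub <- extract_roi(stack, roi_spec(10, 20))
  expect_identical(dim(sub$pixels), c(64L, 64L, 3L))
  expect_identical(sub$pixels[1, 1, 2], stack$pixels[11, 21, 2])
  expect_error(extract_roi(stack, roi_spec(0, 40, 64, 64)), "right edge")
  expect_error(extract_roi(stack, roi_spec(40, 0, 64, 64)), "bottom edge")
})

test_that("DC suppression removes the spatial mean and is idempotent", {
  expect_equal(dc_suppress(matrix(5, 3, 3)), matrix(0, 3, 3))
  f <- rbind(c(3, 1), c(1, 1))
  expect_equal(dc_suppress(f), rbind(c(1.5, -0.5), c(-0.5, -0.5)))
  g <- matrix(rnorm(25), 5, 5)
  expect_equal(dc_suppress(dc_suppress(g)), dc_suppress(g))
})

test_that("the observer template is the mean H1/H0 difference after DC removal", {
  h1 <- array(c(rbind(c(3, 1), c(1, 1)), rbind(c(5, 3), c(3, 3))),
              dim = c(2, 2, 2))
  h0 <- array(c(matrix(1, 2, 2), matrix(3, 2, 2)), dim = c(2, 2, 2))
  tmpl <- build_template(h1, h0)
  expect_equal(tmpl$values, rbind(c(1.5, -0.5), c(-0.5, -0.5)))
  expect_equal(mean(tmpl$values), 0)

  # identical hypotheses give a null template
  expect_equal(build_template(h1, h1)$values, matrix(0, 2, 2))

  # per-frame offsets are invisible to the template
  h1_off <- h1; h1_off[, , 1] <- h1_off[, , 1] + 7
  expect_equal(build_template(h1_off, h0)$values, tmpl$values)

  expect_error(build_template(h1, h0,
                              exclude = list(hypothesis = "h1", index = 1)),
               "at least 2 frames")
})

test_that("frame scoring is the zero-lag cross-correlation after DC removal", {
  tmpl <- build_template(
    array(c(rbind(c(3, 1), c(1, 1)), rbind(c(5, 3), c(3, 3))), c(2, 2, 2)),
    array(c(matrix(1, 2, 2), matrix(3, 2, 2)), c(2, 2, 2)))
  f <- rbind(c(3, 1), c(1, 1))
  expect_equal(score_frame(tmpl, f), 3.0)  # 1.5*1.5 + 3 * 0.25
  expect_equal(score_frame(tmpl, f + 100), 3.0)
  zero <- build_template(array(1, c(2, 2, 2)), array(1, c(2, 2, 2)))
  expect_equal(score_frame(zero, f), 0)
  expect_error(score_frame(tmpl, matrix(0, 3, 3)), "shape")
})

test_that("leave-one-out CDVs equal naive template re-estimation", {
  h1 <- toy_stack(5, seed = 21, offset = 0.5)
  h0 <- toy_stack(5, seed = 22)
  fast <- compute_cdv_series(h1, h0, leave_one_out = TRUE)
  slow <- brute_force_loo_cdvs(h1$pixels, h0$pixels)
  expect_equal(fast$cdv_h1, slow$cdv_h1, tolerance = 1e-12)
  expect_equal(fast$cdv_h0, slow$cdv_h0, tolerance = 1e-12)
  expect_length(fast$cdv_h1, 5)
  expect_length(fast$cdv_h0, 5)
  expect_error(compute_cdv_series(toy_stack(2), toy_stack(2)),
               "at least 3 frames")
})

test_that("high-frequency suppression is recorded and self-adjoint in scoring", {
  h1 <- toy_stack(5, rows = 8, cols = 8, seed = 23, offset = 0.3)
  h0 <- toy_stack(5, rows = 8, cols = 8, seed = 24)
  tmpl <- build_template(h1, h0, hf_cutoff = 0.4)
  expect_match(tmpl$filter_applied, "butterworth")
  expect_lt(abs(mean(tmpl$values)), 1e-9 * max(abs(tmpl$values)))

  # the fast path (filtering the frames) must equal per-frame scoring
  # against the filtered leave-one-out template
  fast <- compute_cdv_series(h1, h0, leave_one_out = TRUE, hf_cutoff = 0.4)
  slow <- brute_force_loo_cdvs(h1$pixels, h0$pixels, hf_cutoff = 0.4)
  expect_equal(fast$cdv_h1, slow$cdv_h1, tolerance = 1e-10)
  expect_equal(fast$cdv_h0, slow$cdv_h0, tolerance = 1e-10)
})

test_that("SNR2_sf matches hand-computed conditional-distribution cases", {
  fp <- 15
  expect_equal(snr_sf(cdv_series(c(1, 2, 3), c(1, 2, 3), fp)), 0)
  expect_equal(snr_sf(cdv_series(c(1, 3), c(-1, 1), fp)), 2.0)
  # means 2 and 0, both variances 1 -> d'^2 = 4
  set.seed(31)
  a <- rnorm(500); a <- (a - mean(a)) / sd(a) + 2
  b <- rnorm(500); b <- (b - mean(b)) / sd(b)
  expect_equal(snr_sf(cdv_series(a, b, fp)), 4.0, tolerance = 1e-10)
  expect_error(snr_sf(cdv_series(c(1, 1), c(0, 0), fp)), "degenerate")
  expect_error(snr_sf(cdv_series(1, c(0, 1), fp)), "at least 2")
})

test_that("SNR2_sf is non-negative, gain/offset invariant, and separates C > 0", {
  cfg <- sim_config(n_frames = 1000, rows = 16, cols = 16, N0 = 100, C = 0.1,
                    detail_diameter_px = 5, seed = 32)
  pair <- simulate_stack(cfg)
  cdvs <- compute_cdv_series(pair$signal_stack, pair$background_stack)
  expect_gt(mean(cdvs$cdv_h1), mean(cdvs$cdv_h0))
  s <- snr_sf(cdvs)
  expect_gte(s, 0)

  # affine rescale of every pixel (detector gain/offset change)
  rescale <- function(st) frame_stack(st$pixels * 3.7 + 120, st$frame_rate_fp)
  cdvs2 <- compute_cdv_series(rescale(pair$signal_stack),
                              rescale(pair$background_stack))
  expect_equal(snr_sf(cdvs2), s, tolerance = 1e-9)
})
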