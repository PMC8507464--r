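# Independent brute-force oracles and small fixture builders.

# Disc area by naive enumeration of every pixel centre (independent of the
# vectorized rasterizer).
brute_force_disc_area <- function(diameter_px, center, grid_shape) {
  r2 <- (diameter_px / 2)^2
  count <- 0L
  for (row in seq_len(grid_shape[1]) - 1L)
    for (col in seq_len(grid_shape[2]) - 1L)
      if ((row - center[1])^2 + (col - center[2])^2 <= r2)
        count <- count + 1L
  count
}

# Leave-one-out CDVs by rebuilding the template from scratch for every
# frame, via the public single-frame operations only.
brute_force_loo_cdvs <- function(h1_arr, h0_arr, fp = 15, hf_cutoff = NULL) {
  n1 <- dim(h1_arr)[3]; n0 <- dim(h0_arr)[3]
  cdv1 <- vapply(seq_len(n1), function(i) {
    tmpl <- build_template(h1_arr, h0_arr,
                           exclude = list(hypothesis = "h1", index = i),
                           hf_cutoff = hf_cutoff)
    score_frame(tmpl, h1_arr[, , i])
  }, 0)
  cdv0 <- vapply(seq_len(n0), function(i) {
    tmpl <- build_template(h1_arr, h0_arr,
                           exclude = list(hypothesis = "h0", index = i),
                           hf_cutoff = hf_cutoff)
    score_frame(tmpl, h0_arr[, , i])
  }, 0)
  cdv_series(cdv1, cdv0, fp)
}

# Random small frame stacks for toy cases.
toy_stack <- function(n, rows = 4, cols = 4, fp = 15, seed = 1, offset = 0) {
  set.seed(seed)
  frame_stack(array(rnorm(rows * cols * n) + offset, dim = c(rows, cols, n)),
              frame_rate_fp = fp)
}

# Stationary AR(1) series with unit marginal variance.
ar1_series <- function(n, alpha, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(n)
  x[1] <- rnorm(1)
  innov <- sqrt(1 - alpha^2)
  for (t in 2:n) x[t] <- alpha * x[t - 1] + innov * rnorm(1)
  x
}

# Simulated pair -> CDV series, the standard measurement path.
sim_cdvs <- function(cfg, ...) {
  pair <- simulate_stack(cfg)
  compute_cdv_series(pair$signal_stack, pair$background_stack, ...)
}
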