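#' Sample autocorrelation of a series
#'
#' Standard biased-normalized sample autocorrelations at lags
#' `1 .. max_lag` (`rho_0 = 1` implied), after mean removal.
#'
#' @param series Numeric vector with `length > max_lag + 1` and non-zero
#'   variance.
#' @param max_lag Largest lag to return (>= 1).
#' @return Numeric vector `rho[1..max_lag]`.
#' @export
autocorrelation <- function(series, max_lag) {
  if (!is_count(max_lag, 1L)) stopf("max_lag must be a positive integer")
  if (length(series) <= max_lag + 1L)
    stopf("series length (%d) must exceed max_lag + 1", length(series))
  if (var(series) == 0) stopf("series has zero variance")
  as.numeric(acf(series, lag.max = max_lag, plot = FALSE,
                 demean = TRUE)$acf)[-1L]
}

# Biased-normalized autocorrelation pooled over independent segments:
# each segment is demeaned, autocovariances are summed over segments and
# normalized by the pooled lag-0 autocovariance.  Avoids spurious
# correlation across segment joins.
.pooled_autocorr <- function(segments, max_lag) {
  segments <- lapply(segments, function(x) x - mean(x))
  gamma0 <- sum(vapply(segments, function(x) sum(x^2), 0))
  if (gamma0 == 0) stopf("series has zero variance")
  vapply(seq_len(max_lag), function(k) {
    sum(vapply(segments, function(x) {
      n <- length(x)
      if (n <= k) 0 else sum(x[seq_len(n - k)] * x[(k + 1):n])
    }, 0)) / gamma0
  }, 0)
}

#' Lag factor: effective independent frames per second
#'
#' Neighbouring fluoroscopy frames are correlated, so the per-frame SNR^2
#' does not accumulate at the pulse rate.  The lag factor
#' `F = f_p / tau`, with `tau = 1 + 2 * sum_k rho_k` the integrated
#' autocorrelation time of the CDV noise series, is the effective number of
#' statistically independent frames per second.  The autocorrelation sum is
#' truncated by the initial-positive-pair-sequence rule: consecutive pair
#' sums `Gamma_m = rho_(2m) + rho_(2m+1)` (starting from
#' `Gamma_0 = 1 + rho_1`) are accumulated while they remain positive, which
#' avoids summing the noise tail.  For uncorrelated frames `F = f_p`; for
#' anti-correlated frames (`rho_1 < 0`) values above `f_p` are possible and
#' returned.  When no lags can be estimated the documented fallback is
#' `F = f_p`.
#'
#' @param cdvs A [cdv_series()]; the H0 series (and, by default, the
#'   mean-removed H1 series) supply the noise autocorrelation.
#' @param include_h1 Pool the mean-removed H1 CDVs with H0 (default `TRUE`;
#'   doubles the sample without mixing in the signal separation).
#' @param max_lag Largest lag entering the sum; default
#'   `min(100, floor(n_min / 4))`.
#' @return Lag factor F in s^-1 (> 0).
#' @export
lag_factor <- function(cdvs, include_h1 = TRUE, max_lag = NULL) {
  if (!inherits(cdvs, "cdv_series")) stopf("cdvs must be a cdv_series")
  n0 <- length(cdvs$cdv_h0)
  if (n0 < 10L) stopf("H0 CDV series too short for lag estimation (%d < 10)", n0)
  if (n0 < 50L)
    warnf("H0 CDV series has only %d frames; lag factor will be noisy (>= 50 recommended)", n0)
  segments <- list(cdvs$cdv_h0)
  if (include_h1) segments <- c(segments, list(cdvs$cdv_h1))
  n_min <- min(lengths(segments))
  if (is.null(max_lag)) max_lag <- min(100L, max(1L, floor(n_min / 4)))
  if (max_lag < 1L) return(cdvs$frame_rate_fp)
  rho <- .pooled_autocorr(segments, max_lag)

  tau <- 1 + 2 * rho[1L]                 # Gamma_0 = 1 + rho_1, always kept
  k <- 2L
  while (k + 1L <= max_lag) {
    g <- rho[k] + rho[k + 1L]
    if (g <= 0) break
    tau <- tau + 2 * g
    k <- k + 2L
  }
  n_total <- sum(lengths(segments))
  tau <- max(tau, 1 / n_total)           # keep F finite for pathological input
  cdvs$frame_rate_fp / tau
}

#' Detectability rate from single-frame SNR^2 and lag factor
#'
#' `SNR2_rate = SNR2_sf * F`, in s^-1: the rate at which squared
#' signal-to-noise ratio accumulates during live viewing.
#'
#' @param snr2_sf Single-frame SNR^2 (>= 0).
#' @param F Lag factor in s^-1 (>= 0).
#' @return SNR^2 rate in s^-1.
#' @export
snr_rate <- function(snr2_sf, F) {
  if (!is_number(snr2_sf) || snr2_sf < 0) stopf("snr2_sf must be >= 0")
  if (!is_number(F) || F < 0) stopf("F must be >= 0")
  snr2_sf * F
}

#' Container for an SNR-rate measurement
#'
#' Holds the single-frame SNR^2, the lag factor, their product
#' `snr2_rate = snr2_sf * lag_F` (enforced exactly), the relative
#' statistical uncertainty and the number of frames used.
#'
#' @param snr2_sf Single-frame SNR^2 (>= 0).
#' @param lag_F Lag factor in s^-1 (>= 0).
#' @param sigma_stat_rel Relative statistical uncertainty (fraction >= 0).
#' @param n_frames_used Total frames entering the estimate.
#' @return Object of class `snr_result`.
#' @export
snr_result <- function(snr2_sf, lag_F, sigma_stat_rel = 0, n_frames_used) {
  if (!is_number(snr2_sf) || snr2_sf < 0) stopf("snr2_sf must be >= 0")
  if (!is_number(lag_F) || lag_F < 0) stopf("lag_F must be >= 0")
  if (!is_number(sigma_stat_rel) || sigma_stat_rel < 0)
    stopf("sigma_stat_rel must be >= 0")
  if (!is_count(n_frames_used, 0L)) stopf("n_frames_used must be a count")
  structure(list(snr2_sf = snr2_sf, lag_F = lag_F,
                 snr2_rate = snr2_sf * lag_F,
                 sigma_stat_rel = sigma_stat_rel,
                 n_frames_used = as.integer(n_frames_used)),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("snr_result: SNR2_sf = %.4g, F = %.4g s^-1, SNR2_rate = %.4g s^-1\n",
              x$snr2_sf, x$lag_F, x$snr2_rate))
  cat(sprintf("  sigma_stat = %.2f%% (%d frames)\n",
              100 * x$sigma_stat_rel, x$n_frames_used))
  invisible(x)
}

# Moving-block resample indices for a series of length n, block length L.
.block_indices <- function(n, block_len) {
  if (block_len >= n) return(seq_len(n))
  nb <- ceiling(n / block_len)
  starts <- sample.int(n - block_len + 1L, nb, replace = TRUE)
  idx <- as.integer(outer(0:(block_len - 1L), starts, "+"))
  idx[seq_len(n)]
}

#' Bootstrap estimate of the relative statistical uncertainty of SNR^2 rate
#'
#' Moving-block bootstrap over the paired CDV sequences: blocks of
#' consecutive frames (block length `ceiling(f_p / F)`, floor 1, so
#' correlated frames are resampled together) are drawn with replacement,
#' `SNR2_rate` is recomputed for each replicate, and the relative spread
#' `sd(replicates) / mean(replicates)` is returned.  Deterministic for a
#' fixed seed.
#'
#' @param cdvs A [cdv_series()] with >= 10 CDVs per hypothesis.
#' @param n_boot Number of bootstrap replicates (>= 200).
#' @param seed RNG seed (optional; caller's RNG state is restored).
#' @param block_len Optional block-length override.
#' @param include_h1 Passed to [lag_factor()].
#' @return Relative statistical uncertainty (fraction).
#' @export
bootstrap_sigma_stat <- function(cdvs, n_boot = 500L, seed = NULL,
                                 block_len = NULL, include_h1 = TRUE) {
  if (!inherits(cdvs, "cdv_series")) stopf("cdvs must be a cdv_series")
  n1 <- length(cdvs$cdv_h1); n0 <- length(cdvs$cdv_h0)
  if (n1 < 10L || n0 < 10L)
    stopf("need at least 10 CDVs per hypothesis (got %d and %d)", n1, n0)
  if (!is_count(n_boot, 200L)) stopf("n_boot must be an integer >= 200")
  snr_sf(cdvs)                           # propagate degenerate-input errors
  f_hat <- suppressWarnings(lag_factor(cdvs, include_h1 = include_h1))
  if (is.null(block_len))
    block_len <- max(1L, as.integer(ceiling(cdvs$frame_rate_fp / f_hat)))
  max_lag <- min(50L, max(1L, floor(min(n1, n0) / 4)))
  vals <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i1 <- .block_indices(n1, block_len)
      i0 <- if (n0 == n1) i1 else .block_indices(n0, block_len)
      rep_cdvs <- cdv_series(cdvs$cdv_h1[i1], cdvs$cdv_h0[i0],
                             cdvs$frame_rate_fp)
      s <- tryCatch(snr_sf(rep_cdvs), error = function(e) NA_real_)
      if (is.na(s)) return(NA_real_)
      f <- tryCatch(
        suppressWarnings(lag_factor(rep_cdvs, include_h1 = include_h1,
                                    max_lag = max_lag)),
        error = function(e) cdvs$frame_rate_fp)
      s * f
    }, 0)
  })
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2L) stopf("too few valid bootstrap replicates")
  sd(vals) / mean(vals)
}

#' End-to-end SNR-rate measurement from paired frame stacks
#'
#' Convenience wrapper chaining ROI extraction, CDV computation, the
#' single-frame SNR^2, the lag factor, and (optionally) the block-bootstrap
#' statistical uncertainty into a single [snr_result()].
#'
#' @param signal_stack A [frame_stack()] containing the detail, or a
#'   `stack_pair` from [simulate_stack()] (then `background_stack` may be
#'   omitted).
#' @param background_stack A [frame_stack()] without the detail.
#' @param signal_roi Optional [roi_spec()] applied to the signal stack.
#' @param background_roi Optional [roi_spec()] or list of them (multiple
#'   background ROIs are pooled along the frame axis).
#' @param leave_one_out,hf_cutoff Passed to [compute_cdv_series()].
#' @param include_h1 Passed to [lag_factor()].
#' @param n_boot Bootstrap replicates for the statistical uncertainty;
#'   `0` (default) skips the bootstrap and reports `sigma_stat_rel = 0`.
#' @param seed Seed for the bootstrap.
#' @return An [snr_result()].
#' @export
measure_snr <- function(signal_stack, background_stack = NULL,
                        signal_roi = NULL, background_roi = NULL,
                        leave_one_out = TRUE, hf_cutoff = NULL,
                        include_h1 = TRUE, n_boot = 0L, seed = NULL) {
  if (inherits(signal_stack, "stack_pair")) {
    background_stack <- signal_stack$background_stack
    signal_stack <- signal_stack$signal_stack
  }
  if (is.null(background_stack)) stopf("background_stack is required")
  if (!is.null(signal_roi)) signal_stack <- extract_roi(signal_stack, signal_roi)
  if (!is.null(background_roi)) {
    rois <- if (inherits(background_roi, "roi_spec")) list(background_roi)
            else background_roi
    subs <- lapply(rois, function(r) extract_roi(background_stack, r)$pixels)
    background_stack <- frame_stack(
      array(unlist(subs, use.names = FALSE),
            dim = c(dim(subs[[1]])[1:2], sum(vapply(subs, function(a) dim(a)[3], 0)))),
      background_stack$frame_rate_fp, background_stack$pixel_pitch_mm,
      provenance = background_stack$provenance)
  }
  cdvs <- compute_cdv_series(signal_stack, background_stack,
                             leave_one_out = leave_one_out,
                             hf_cutoff = hf_cutoff)
  s <- snr_sf(cdvs)
  f <- lag_factor(cdvs, include_h1 = include_h1)
  sig <- if (n_boot > 0)
    bootstrap_sigma_stat(cdvs, n_boot = n_boot, seed = seed,
                         include_h1 = include_h1) else 0
  snr_result(s, f, sig, length(cdvs$cdv_h1) + length(cdvs$cdv_h0))
}
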