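#' Configuration for a synthetic contrast-detail fluoroscopy acquisition
#'
#' Bundles every parameter of the pulsed-fluoroscopy phantom simulator: a
#' uniform quantum-noise background of mean count `N0` per pixel, a
#' cylindrical (disc) low-contrast detail of relative contrast `C` and
#' diameter `detail_diameter_px` at the detector plane, optional Gaussian
#' system blur of the mean image, and optional AR(1) frame-to-frame noise
#' correlation at pulse rate `frame_rate_fp`.
#'
#' Geometric magnification `M` enters detection only by rescaling the
#' projected detail area, so it is carried as metadata and the diameter is
#' specified directly at the detector plane
#' (`detail_diameter_px = M * physical diameter / pixel pitch`).
#'
#' @param n_frames Number of frames per hypothesis (>= 2).
#' @param rows,cols Grid size in pixels.
#' @param N0 Mean background count per pixel (> 0); proxy for the detector
#'   air-kerma per frame.
#' @param C Signed relative contrast of the detail, `|C| < 1`. A negative
#'   value models an attenuating detail; detectability depends only on `C^2`.
#' @param detail_diameter_px Disc diameter in pixels at the detector plane.
#' @param M Geometric magnification (>= 1, metadata only; see Details).
#' @param psf_sigma_px Gaussian blur sigma applied to the mean image
#'   (pixels, >= 0; 0 disables blur).
#' @param ar1_alpha Lag-1 temporal correlation of the noise, in `[0, 1)`.
#' @param frame_rate_fp Pulse rate f_p in s^-1 (> 0).
#' @param seed RNG seed for reproducible stacks (optional).
#' @param center Disc centre as `c(row, col)` in 0-based pixel coordinates;
#'   defaults to the grid centre.
#' @return An object of class `sim_config`.
#' @seealso [simulate_stack()], [analytic_ideal_snr_sf()], [analytic_lag_ar1()]
#' @export
sim_config <- function(n_frames, rows = 64L, cols = 64L, N0, C,
                       detail_diameter_px, M = 1, psf_sigma_px = 0,
                       ar1_alpha = 0, frame_rate_fp = 15, seed = NULL,
                       center = NULL) {
  if (!is_count(n_frames, 2L)) stopf("n_frames must be an integer >= 2")
  if (!is_count(rows, 1L) || !is_count(cols, 1L))
    stopf("rows and cols must be positive integers")
  if (!is_number(N0) || N0 <= 0) stopf("N0 must be > 0")
  if (!is_number(C) || abs(C) >= 1) stopf("C must satisfy |C| < 1")
  if (!is_number(detail_diameter_px) || detail_diameter_px <= 0)
    stopf("detail_diameter_px must be > 0")
  if (!is_number(M) || M < 1) stopf("M must be >= 1")
  if (!is_number(psf_sigma_px) || psf_sigma_px < 0)
    stopf("psf_sigma_px must be >= 0")
  if (!is_number(ar1_alpha) || ar1_alpha < 0 || ar1_alpha >= 1)
    stopf("ar1_alpha must lie in [0, 1)")
  if (!is_number(frame_rate_fp) || frame_rate_fp <= 0)
    stopf("frame_rate_fp must be > 0")
  if (is.null(center)) center <- c((rows - 1) / 2, (cols - 1) / 2)
  if (length(center) != 2L || !all(is.finite(center)))
    stopf("center must be c(row, col)")
  cfg <- structure(
    list(n_frames = as.integer(n_frames), rows = as.integer(rows),
         cols = as.integer(cols), N0 = N0, C = C,
         detail_diameter_px = detail_diameter_px, M = M,
         psf_sigma_px = psf_sigma_px, ar1_alpha = ar1_alpha,
         frame_rate_fp = frame_rate_fp,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         center = as.numeric(center)),
    class = "sim_config")
  # validates that the disc fits inside the grid
  render_disc_mask(detail_diameter_px, cfg$center, c(rows, cols))
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d frames of %dx%d px | N0=%g, C=%g, disc d=%g px (M=%g)\n",
    x$n_frames, x$rows, x$cols, x$N0, x$C, x$detail_diameter_px, x$M))
  cat(sprintf("  psf_sigma=%g px, ar1_alpha=%g, f_p=%g s^-1, seed=%s\n",
              x$psf_sigma_px, x$ar1_alpha, x$frame_rate_fp,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Rasterize a disc as a binary pixel mask
#'
#' A pixel belongs to the disc iff its centre lies within `diameter_px / 2`
#' of `center` (pixel-centre inclusion, the simplest deterministic
#' rasterization convention).  Coordinates are 0-based `(row, col)`; pixel
#' `(r, c)` has its centre at `(r, c)` and extends half a pixel each way.
#'
#' By default a disc whose continuous outline extends beyond the pixel grid
#' is rejected, since a clipped detail invalidates area-based oracles.  Set
#' `clip = TRUE` to rasterize the intersection instead (e.g. a saturating
#' disc larger than the grid).
#'
#' @param diameter_px Disc diameter in pixels (> 0).
#' @param center Disc centre `c(row, col)`, 0-based.
#' @param grid_shape Grid size `c(rows, cols)`.
#' @param clip Allow the disc to extend beyond the grid (default `FALSE`).
#' @return Logical `rows x cols` matrix; the rasterized area is `sum(mask)`.
#' @examples
#' sum(render_disc_mask(6, c(32, 32), c(64, 64)))  # close to pi * 3^2
#' @export
render_disc_mask <- function(diameter_px, center, grid_shape, clip = FALSE) {
  if (!is_number(diameter_px) || diameter_px <= 0)
    stopf("diameter_px must be > 0")
  rows <- grid_shape[1]; cols <- grid_shape[2]
  r <- diameter_px / 2
  if (!clip) {
    lo_r <- center[1] - r; hi_r <- center[1] + r
    lo_c <- center[2] - r; hi_c <- center[2] + r
    if (lo_r < -0.5 || lo_c < -0.5 || hi_r > rows - 0.5 || hi_c > cols - 0.5)
      stopf(paste0("disc (diameter %g at centre %g,%g) extends beyond the ",
                   "%dx%d grid; shrink it or pass clip = TRUE"),
            diameter_px, center[1], center[2], rows, cols)
  }
  dr2 <- (seq_len(rows) - 1 - center[1])^2
  dc2 <- (seq_len(cols) - 1 - center[2])^2
  outer(dr2, dc2, "+") <= r^2
}

# Generate an n-frame noise stack about mean image `mu` (P = length(mu)).
# alpha = 0: exact per-pixel Poisson draws.
# alpha > 0: stationary Gaussian AR(1) noise with per-pixel variance equal
# to the mean (valid quantum-noise surrogate for N0 >~ 20); negative counts
# are clipped at zero and counted.
.sim_noise_stack <- function(mu, n_frames, alpha) {
  p <- length(mu)
  if (alpha == 0) {
    pix <- rpois(p * n_frames, lambda = rep(as.numeric(mu), n_frames))
    clipped <- 0L
  } else {
    sd_pix <- sqrt(as.numeric(mu))
    noise <- matrix(0, p, n_frames)
    noise[, 1L] <- rnorm(p)
    innov_sd <- sqrt(1 - alpha^2)
    for (t in seq_len(n_frames)[-1L])
      noise[, t] <- alpha * noise[, t - 1L] + innov_sd * rnorm(p)
    pix <- as.numeric(mu) + sd_pix * as.numeric(noise)
    clipped <- sum(pix < 0)
    if (clipped > 0) pix[pix < 0] <- 0
  }
  list(pixels = array(pix, dim = c(dim(mu), n_frames)),
       clipped = as.integer(clipped))
}

#' Simulate paired signal-present / signal-absent fluoroscopy stacks
#'
#' Generates two independent frame stacks under identical acquisition
#' conditions: one containing the low-contrast disc (hypothesis H1) and one
#' without it (H0).  The background mean is `N0` everywhere; inside the disc
#' the mean is `N0 * (1 + C)`.  Optional Gaussian blur is applied to the
#' mean (noise-free) image only, so the quantum noise stays white and the
#' analytic single-frame oracle remains valid.  Per-frame noise is Poisson
#' about the mean image; with `ar1_alpha > 0` it is replaced by a Gaussian
#' AR(1) process with stationary per-pixel variance equal to the mean, which
#' preserves the Poisson variance-mean relation while giving the lag factor
#' a closed-form oracle.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `stack_pair`: list with `signal_stack` and
#'   `background_stack` (both [frame_stack()]), `truth` (the config) and
#'   `n_clipped` (pixels clipped at zero by the Gaussian branch).
#' @export
simulate_stack <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stopf("cfg must be a sim_config")
  mask <- render_disc_mask(cfg$detail_diameter_px, cfg$center,
                           c(cfg$rows, cfg$cols))
  mu_bg <- matrix(cfg$N0, cfg$rows, cfg$cols)
  mu_sig <- cfg$N0 * (1 + cfg$C * mask)
  if (cfg$psf_sigma_px > 0)
    mu_sig <- EBImage::gblur(mu_sig, sigma = cfg$psf_sigma_px)
  out <- with_local_seed(cfg$seed, {
    sig <- .sim_noise_stack(mu_sig, cfg$n_frames, cfg$ar1_alpha)
    bg <- .sim_noise_stack(mu_bg, cfg$n_frames, cfg$ar1_alpha)
    list(sig = sig, bg = bg)
  })
  n_clipped <- c(signal = out$sig$clipped, background = out$bg$clipped)
  if (sum(n_clipped) > 0)
    warnf("%d negative pixel values clipped at 0 (N0 may be too small for the Gaussian AR(1) branch)",
          sum(n_clipped))
  structure(
    list(signal_stack = frame_stack(out$sig$pixels, cfg$frame_rate_fp,
                                    provenance = "simulate_stack:H1"),
         background_stack = frame_stack(out$bg$pixels, cfg$frame_rate_fp,
                                        provenance = "simulate_stack:H0"),
         truth = cfg, n_clipped = n_clipped),
    class = "stack_pair")
}

#' Analytic ideal-observer single-frame SNR^2 for an unblurred disc
#'
#' For a disc of rasterized area `A_px` pixels, small relative contrast `C`
#' and Poisson background mean `N0`, the ideal observer's single-frame
#' detectability is the Rose-model value
#' `SNR2_sf = A_px * C^2 * N0` (sum over the disc of `(C * N0)^2 / N0`).
#' Valid only for unblurred quantum noise, so blurred configurations are
#' rejected.
#'
#' @param cfg A [sim_config()] with `psf_sigma_px = 0`.
#' @return Expected single-frame SNR^2 (dimensionless).
#' @export
analytic_ideal_snr_sf <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stopf("cfg must be a sim_config")
  if (cfg$psf_sigma_px > 0)
    stopf("analytic oracle is undefined for blurred configurations (psf_sigma_px > 0)")
  a_px <- sum(render_disc_mask(cfg$detail_diameter_px, cfg$center,
                               c(cfg$rows, cfg$cols)))
  a_px * cfg$C^2 * cfg$N0
}

#' Analytic lag factor of an AR(1) frame sequence
#'
#' For noise with lag-1 frame correlation `alpha`, the effective number of
#' independent frames per second is
#' `F = f_p * (1 - alpha) / (1 + alpha)`
#' (the effective-sample-size rate of an AR(1) process, since its integrated
#' autocorrelation time is `(1 + alpha) / (1 - alpha)`).  Uncorrelated
#' frames give `F = f_p`; fully correlated frames give `F -> 0`.
#'
#' @param alpha AR(1) coefficient in `[0, 1)`.
#' @param frame_rate_fp Pulse rate f_p in s^-1.
#' @return Expected lag factor F in s^-1.
#' @export
analytic_lag_ar1 <- function(alpha, frame_rate_fp) {
  if (!is_number(alpha) || alpha < 0 || alpha >= 1)
    stopf("alpha must lie in [0, 1)")
  if (!is_number(frame_rate_fp) || frame_rate_fp <= 0)
    stopf("frame_rate_fp must be > 0")
  frame_rate_fp * (1 - alpha) / (1 + alpha)
}
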