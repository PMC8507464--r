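#' Frame stack container
#'
#' A stack of equally shaped fluoroscopy frames with its pulse (frame) rate.
#' Pixels are stored as a `rows x cols x frames` numeric array; frame order
#' follows acquisition time.
#'
#' @param pixels 3-D numeric array `rows x cols x frames` (>= 2 frames), or
#'   a list of equally shaped matrices.
#' @param frame_rate_fp Frame (pulse) rate in s^-1 (> 0).
#' @param pixel_pitch_mm Optional detector pixel pitch in mm.
#' @param provenance Free-text origin of the stack.
#' @return Object of class `frame_stack`.
#' @export
frame_stack <- function(pixels, frame_rate_fp, pixel_pitch_mm = NULL,
                        provenance = "") {
  if (is.list(pixels)) {
    dims <- unique(lapply(pixels, dim))
    if (length(dims) != 1L) stopf("all frames must share the same shape")
    pixels <- array(unlist(pixels, use.names = FALSE),
                    dim = c(dims[[1]], length(pixels)))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stopf("pixels must be a rows x cols x frames array")
  if (dim(pixels)[3] < 2L) stopf("a frame stack needs at least 2 frames")
  if (!is_number(frame_rate_fp) || frame_rate_fp <= 0)
    stopf("frame_rate_fp must be > 0")
  structure(list(pixels = pixels, frame_rate_fp = frame_rate_fp,
                 pixel_pitch_mm = pixel_pitch_mm, provenance = provenance),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("frame_stack: %d frames of %dx%d px at %g s^-1%s\n",
              d[3], d[1], d[2], x$frame_rate_fp,
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

n_frames <- function(stack) dim(stack$pixels)[3]

# rows x cols x frames array -> (rows*cols) x frames matrix
.frame_matrix <- function(stack) {
  d <- dim(stack$pixels)
  matrix(stack$pixels, nrow = d[1] * d[2], ncol = d[3])
}

#' Rectangular region-of-interest specification
#'
#' 0-based, top-left-origin, half-open extents: the ROI covers pixel rows
#' `top .. top + height - 1` and columns `left .. left + width - 1`.
#' The conventional analysis ROI is 64 x 64 pixels.
#'
#' @param top,left 0-based pixel offsets (>= 0).
#' @param height,width ROI size in pixels (>= 1); default 64.
#' @return Object of class `roi_spec`.
#' @export
roi_spec <- function(top, left, height = 64L, width = 64L) {
  if (!is_count(top) || !is_count(left))
    stopf("top and left must be non-negative integers")
  if (!is_count(height, 1L) || !is_count(width, 1L))
    stopf("height and width must be positive integers")
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi_spec")
}

#' Extract a region of interest from a frame stack
#'
#' Returns the ROI sub-stack, frames in original order, without resampling.
#'
#' @param stack A [frame_stack()].
#' @param roi A [roi_spec()].
#' @return A [frame_stack()] of shape `height x width x frames`.
#' @export
extract_roi <- function(stack, roi) {
  if (!inherits(stack, "frame_stack")) stopf("stack must be a frame_stack")
  if (!inherits(roi, "roi_spec")) stopf("roi must be a roi_spec")
  d <- dim(stack$pixels)
  if (roi$top + roi$height > d[1])
    stopf("ROI bottom edge (top %d + height %d) exceeds the %d frame rows",
          roi$top, roi$height, d[1])
  if (roi$left + roi$width > d[2])
    stopf("ROI right edge (left %d + width %d) exceeds the %d frame columns",
          roi$left, roi$width, d[2])
  sub <- stack$pixels[roi$top + seq_len(roi$height),
                      roi$left + seq_len(roi$width), , drop = FALSE]
  frame_stack(sub, stack$frame_rate_fp, stack$pixel_pitch_mm,
              provenance = stack$provenance)
}

#' Remove the DC (spatial mean) component of a frame
#'
#' Subtracts the frame's spatial mean so the output has exactly zero mean.
#' Applying it to both template inputs and scored frames makes the decision
#' variables invariant to frame-to-frame offset drift.  Idempotent.
#'
#' @param roi_frame Numeric matrix.
#' @return Matrix of the same shape with zero spatial mean.
#' @export
dc_suppress <- function(roi_frame) {
  if (!is.matrix(roi_frame)) roi_frame <- as.matrix(roi_frame)
  roi_frame - mean(roi_frame)
}

# Radially symmetric Butterworth low-pass (order `order`) applied in the
# frequency domain; `cutoff` is the -3 dB radius as a fraction of Nyquist.
.butterworth_lowpass <- function(m, cutoff, order = 4) {
  if (!is_number(cutoff) || cutoff <= 0 || cutoff > 1)
    stopf("hf_cutoff must lie in (0, 1] (fraction of Nyquist)")
  d <- dim(m)
  freq1 <- function(n) { f <- (seq_len(n) - 1) / n; f[f > 0.5] <- f[f > 0.5] - 1; f }
  rad <- sqrt(outer(freq1(d[1])^2, freq1(d[2])^2, "+")) # cycles/pixel
  h <- 1 / (1 + (rad / (cutoff * 0.5))^(2 * order))
  Re(fft(fft(m) * h, inverse = TRUE)) / length(m)
}

#' Build the quasi-ideal observer template
#'
#' The template is the difference between the mean DC-suppressed
#' signal-present (H1) frames and the mean DC-suppressed signal-absent (H0)
#' frames — the matched filter of the SKE/BKE detection task.  A frame can
#' be excluded from the averaging (used by the leave-one-out scorer to
#' avoid correlating a frame with its own template).  Optionally a
#' radially symmetric 4th-order Butterworth low-pass at `hf_cutoff` x
#' Nyquist suppresses high spatial frequencies, where the template carries
#' mostly noise; the filter applied is recorded in `filter_applied`.
#'
#' @param h1_rois,h0_rois ROI-sized [frame_stack()]s (or 3-D arrays) of
#'   signal-present and signal-absent frames.
#' @param exclude Optional `list(hypothesis = "h1"|"h0", index = i)` naming
#'   one frame to leave out.
#' @param hf_cutoff Optional low-pass cutoff as a fraction of Nyquist in
#'   `(0, 1]`; `NULL` (default) disables high-frequency suppression.
#' @return Object of class `observer_template` with `values` (matrix, zero
#'   spatial mean) and `filter_applied`.
#' @export
build_template <- function(h1_rois, h0_rois, exclude = NULL,
                           hf_cutoff = NULL) {
  a1 <- if (inherits(h1_rois, "frame_stack")) h1_rois$pixels else h1_rois
  a0 <- if (inherits(h0_rois, "frame_stack")) h0_rois$pixels else h0_rois
  if (!identical(dim(a1)[1:2], dim(a0)[1:2]))
    stopf("H1 and H0 ROI shapes differ")
  shape <- dim(a1)[1:2]
  m1 <- matrix(a1, nrow = prod(shape)); m0 <- matrix(a0, nrow = prod(shape))
  if (!is.null(exclude)) {
    hyp <- match.arg(exclude$hypothesis, c("h1", "h0"))
    i <- exclude$index
    if (hyp == "h1") {
      if (!is_count(i, 1L) || i > ncol(m1)) stopf("exclude index out of range")
      m1 <- m1[, -i, drop = FALSE]
    } else {
      if (!is_count(i, 1L) || i > ncol(m0)) stopf("exclude index out of range")
      m0 <- m0[, -i, drop = FALSE]
    }
  }
  if (ncol(m1) < 2L || ncol(m0) < 2L)
    stopf("need at least 2 frames per hypothesis after exclusion")
  dc <- function(m) sweep(m, 2L, colMeans(m))
  vals <- matrix(rowMeans(dc(m1)) - rowMeans(dc(m0)), shape[1], shape[2])
  filter_applied <- "dc_suppression"
  if (!is.null(hf_cutoff)) {
    vals <- .butterworth_lowpass(vals, hf_cutoff)
    filter_applied <- sprintf("dc_suppression+butterworth4_lowpass@%gNyquist",
                              hf_cutoff)
  }
  structure(list(values = vals, filter_applied = filter_applied),
            class = "observer_template")
}

#' Score one frame against an observer template
#'
#' The conditional decision variable (CDV) is the zero-lag cross-correlation
#' of the template with the DC-suppressed frame:
#' `CDV = sum(template * dc_suppress(frame))`.  Adding a constant to the
#' frame leaves the CDV unchanged.
#'
#' @param template An [build_template()] result (or plain matrix).
#' @param roi_frame Matrix of the same shape as the template.
#' @return The CDV (scalar).
#' @export
score_frame <- function(template, roi_frame) {
  tv <- if (inherits(template, "observer_template")) template$values
        else template
  if (!identical(dim(tv), dim(as.matrix(roi_frame))))
    stopf("frame shape (%s) does not match template shape (%s)",
          paste(dim(as.matrix(roi_frame)), collapse = "x"),
          paste(dim(tv), collapse = "x"))
  sum(tv * dc_suppress(roi_frame))
}

#' Conditional decision variable series
#'
#' Paired per-frame CDV sequences under the signal-present (H1) and
#' signal-absent (H0) hypotheses, in acquisition order.
#'
#' @param cdv_h1,cdv_h0 Numeric vectors of CDVs.
#' @param frame_rate_fp Frame (pulse) rate in s^-1.
#' @return Object of class `cdv_series`.
#' @export
cdv_series <- function(cdv_h1, cdv_h0, frame_rate_fp) {
  if (!length(cdv_h1) || !length(cdv_h0))
    stopf("both CDV sequences must be non-empty")
  if (!is_number(frame_rate_fp) || frame_rate_fp <= 0)
    stopf("frame_rate_fp must be > 0")
  structure(list(cdv_h1 = as.numeric(cdv_h1), cdv_h0 = as.numeric(cdv_h0),
                 frame_rate_fp = frame_rate_fp),
            class = "cdv_series")
}

#' Compute the observer's CDV series for paired frame stacks
#'
#' Scores every frame under each hypothesis against the observer template.
#' With `leave_one_out = TRUE` (default) each frame is scored against the
#' template rebuilt with that frame excluded, eliminating the optimistic
#' bias of correlating a frame with a template it helped form.  The
#' leave-one-out means are updated by a running-sum downdate, which equals
#' naive recomputation to machine precision.
#'
#' @param h1_stack,h0_stack ROI-sized [frame_stack()]s for the
#'   signal-present and signal-absent conditions (same shape, same rate).
#' @param leave_one_out Score each frame with itself excluded from the
#'   template (default `TRUE`; needs >= 3 frames per hypothesis).
#' @param hf_cutoff Optional Butterworth low-pass cutoff for the template,
#'   as in [build_template()].
#' @return A [cdv_series()].
#' @export
compute_cdv_series <- function(h1_stack, h0_stack, leave_one_out = TRUE,
                               hf_cutoff = NULL) {
  if (!inherits(h1_stack, "frame_stack") || !inherits(h0_stack, "frame_stack"))
    stopf("h1_stack and h0_stack must be frame_stack objects")
  if (!identical(dim(h1_stack$pixels)[1:2], dim(h0_stack$pixels)[1:2]))
    stopf("H1 and H0 ROI shapes differ")
  if (h1_stack$frame_rate_fp != h0_stack$frame_rate_fp)
    stopf("H1 and H0 stacks have different frame rates")
  n1 <- n_frames(h1_stack); n0 <- n_frames(h0_stack)
  min_needed <- if (leave_one_out) 3L else 2L
  if (n1 < min_needed || n0 < min_needed)
    stopf("need at least %d frames per hypothesis (got %d and %d)",
          min_needed, n1, n0)

  g1 <- .frame_matrix(h1_stack); g0 <- .frame_matrix(h0_stack)
  g1 <- sweep(g1, 2L, colMeans(g1))       # DC-suppressed frames, P x n
  g0 <- sweep(g0, 2L, colMeans(g0))
  # With HF suppression the template is low-passed; because the filter is
  # real and radially symmetric it is self-adjoint, so scoring a raw frame
  # against the filtered template equals scoring the filtered frame against
  # the raw template.  Frames are filtered once, templates left raw.
  if (!is.null(hf_cutoff)) {
    d <- dim(h1_stack$pixels)[1:2]
    lp <- function(m) {
      for (j in seq_len(ncol(m)))
        m[, j] <- as.numeric(.butterworth_lowpass(matrix(m[, j], d[1], d[2]),
                                                  hf_cutoff))
      m
    }
    g1s <- lp(g1); g0s <- lp(g0)
  } else {
    g1s <- g1; g0s <- g0
  }
  s1 <- rowSums(g1); s0 <- rowSums(g0)
  if (leave_one_out) {
    # <T_{-i}, f_i> with T_{-i} = (S1 - f_i)/(n1-1) - S0/n0 for H1 frames
    cdv1 <- (as.numeric(crossprod(g1s, s1)) - colSums(g1 * g1s)) / (n1 - 1) -
      as.numeric(crossprod(g1s, s0)) / n0
    cdv0 <- as.numeric(crossprod(g0s, s1)) / n1 -
      (as.numeric(crossprod(g0s, s0)) - colSums(g0 * g0s)) / (n0 - 1)
  } else {
    tmpl <- s1 / n1 - s0 / n0
    cdv1 <- as.numeric(crossprod(g1s, tmpl))
    cdv0 <- as.numeric(crossprod(g0s, tmpl))
  }
  cdv_series(cdv1, cdv0, h1_stack$frame_rate_fp)
}

#' Single-frame squared SNR from the two CDV distributions
#'
#' The detectability index of the binary detection task,
#' `SNR2_sf = (mean(CDV_H1) - mean(CDV_H0))^2 /
#'            (0.5 * (var(CDV_H1) + var(CDV_H0)))`,
#' using unbiased (n-1) sample variances.  This is the squared separation
#' of the two conditional distributions in units of their pooled spread
#' (d'^2 under the normality assumption).
#'
#' @param cdvs A [cdv_series()] with >= 2 CDVs per hypothesis.
#' @return SNR^2 per frame (dimensionless, >= 0).
#' @export
snr_sf <- function(cdvs) {
  if (!inherits(cdvs, "cdv_series")) stopf("cdvs must be a cdv_series")
  if (length(cdvs$cdv_h1) < 2L || length(cdvs$cdv_h0) < 2L)
    stopf("need at least 2 CDVs per hypothesis")
  v1 <- var(cdvs$cdv_h1); v0 <- var(cdvs$cdv_h0)
  if (v1 == 0 && v0 == 0)
    stopf("both CDV distributions are degenerate (zero variance)")
  (mean(cdvs$cdv_h1) - mean(cdvs$cdv_h0))^2 / (0.5 * (v1 + v0))
}
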