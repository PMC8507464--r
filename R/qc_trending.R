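#' Quality-control measurement series
#'
#' Repeated measurements of one metric (e.g. `SNR2_rate` or `P_KA,rate`)
#' over time, for constancy-check trending.
#'
#' @param timestamps Ordered dates/times (anything coercible for plotting).
#' @param values Numeric measurements, same length.
#' @param label Metric name and units.
#' @return Object of class `qc_series`.
#' @export
qc_series <- function(timestamps, values, label = "metric") {
  if (length(timestamps) != length(values))
    stopf("timestamps and values must have the same length")
  if (!is.numeric(values)) stopf("values must be numeric")
  structure(list(timestamps = timestamps, values = as.numeric(values),
                 label = label),
            class = "qc_series")
}

#' Control limits for a constancy check
#'
#' Mean and `mean +/- k_sd * SD` limits (SD with n-1 denominator), as drawn
#' on a control chart.  A baseline subset of points may be frozen and its
#' limits applied to later measurements; by default the full series is used.
#'
#' @param series A [qc_series()] (or numeric vector) with >= 2 points.
#' @param k_sd Limit width in standard deviations (default 2).
#' @param baseline Optional integer indices of the baseline period.
#' @return Object of class `qc_limits`: list(mean, sd, lower, upper, k_sd).
#' @export
control_limits <- function(series, k_sd = 2, baseline = NULL) {
  x <- if (inherits(series, "qc_series")) series$values else as.numeric(series)
  if (!is_number(k_sd) || k_sd < 0) stopf("k_sd must be >= 0")
  if (!is.null(baseline)) x <- x[baseline]
  if (length(x) < 2L) stopf("need at least 2 points for control limits")
  m <- mean(x); s <- sd(x)
  structure(list(mean = m, sd = s, lower = m - k_sd * s,
                 upper = m + k_sd * s, k_sd = k_sd),
            class = "qc_limits")
}

#' Flag points outside control limits
#'
#' A point is flagged iff it lies strictly outside `[lower, upper]`; a
#' point exactly on a limit is not flagged (a value at +/- k SD is not by
#' itself evidence of drift).
#'
#' @param series A [qc_series()] (or numeric vector).
#' @param limits A [control_limits()] result.
#' @return Logical vector, `TRUE` for out-of-control points.
#' @export
flag_points <- function(series, limits) {
  x <- if (inherits(series, "qc_series")) series$values else as.numeric(series)
  if (!inherits(limits, "qc_limits")) stopf("limits must come from control_limits()")
  x < limits$lower | x > limits$upper
}

#' Ordinary-least-squares linearity check of a response sweep
#'
#' Fits `metric ~ covariate` by OLS and reports slope, intercept, their
#' standard errors and R^2.  The `zero_intercept` flag is `TRUE` when the
#' intercept is consistent with zero (`|intercept| < 2 * SE(intercept)`),
#' the signature of a proportional (Rose-model) response.
#'
#' @param x Covariate values (>= 3 points), or a two-column data frame.
#' @param y Metric values (ignored when `x` is a data frame).
#' @return Object of class `sweep_result`: slope, intercept, their SEs,
#'   `r_squared`, `zero_intercept`, and the underlying `lm` fit.
#' @export
sweep_linearity <- function(x, y = NULL) {
  if (is.data.frame(x)) { y <- x[[2]]; x <- x[[1]] }
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stopf("x and y must have the same length")
  if (length(x) < 3L) stopf("need at least 3 points for a linearity sweep")
  fit <- lm(y ~ x)
  # summary() warns on an exact fit; that case is legitimate here
  sm <- suppressWarnings(summary(fit))
  ct <- sm$coefficients
  intercept <- ct[1, 1]; int_se <- ct[1, 2]
  # an exact fit has SE 0; an intercept negligible against the response
  # scale still counts as zero
  zero_int <- abs(intercept) < 2 * int_se ||
    abs(intercept) <= 1e-8 * max(abs(y))
  structure(list(slope = ct[2, 1], slope_se = ct[2, 2],
                 intercept = intercept, intercept_se = int_se,
                 r_squared = sm$r.squared,
                 zero_intercept = zero_int,
                 fit = fit),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: slope %.4g +/- %.2g, intercept %.4g +/- %.2g, R^2 = %.4f%s\n",
              x$slope, x$slope_se, x$intercept, x$intercept_se, x$r_squared,
              if (x$zero_intercept) " (intercept ~ 0)" else ""))
  invisible(x)
}

#' Read a QC measurement log
#'
#' Expects a CSV with columns `date`, `metric`, `value` and optionally
#' `units`; use [as_qc_series()] to pull one metric out as a series.
#'
#' @param path CSV file path.
#' @return Data frame of the log.
#' @export
read_qc_log <- function(path) {
  if (!file.exists(path)) stopf("QC log not found: %s", path)
  log <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "metric", "value")
  if (!all(need %in% names(log)))
    stopf("QC log must have columns %s", paste(need, collapse = ", "))
  log
}

#' Extract one metric from a QC log as a series
#'
#' @param log Data frame from [read_qc_log()].
#' @param metric Metric name to select.
#' @return A [qc_series()].
#' @export
as_qc_series <- function(log, metric) {
  rows <- log[log$metric == metric, , drop = FALSE]
  if (!nrow(rows)) stopf("metric '%s' not present in the log", metric)
  units <- if ("units" %in% names(rows) && nzchar(rows$units[1]))
    paste0(" [", rows$units[1], "]") else ""
  qc_series(rows$date, rows$value, label = paste0(metric, units))
}

#' Draw a control chart
#'
#' Base-graphics constancy chart: measurements in time order, solid mean
#' line, dashed `+/- k SD` limits, out-of-control points highlighted.
#'
#' @param series A [qc_series()].
#' @param limits Optional [control_limits()]; computed from the series if
#'   missing.
#' @param file Optional PNG path; plots to the active device when `NULL`.
#' @return The limits, invisibly.
#' @export
plot_control_chart <- function(series, limits = NULL, file = NULL) {
  if (!inherits(series, "qc_series")) stopf("series must be a qc_series")
  if (is.null(limits)) limits <- control_limits(series)
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 480)
    on.exit(grDevices::dev.off())
  }
  n <- length(series$values)
  flags <- flag_points(series, limits)
  graphics::plot(seq_len(n), series$values, type = "b", pch = 19,
                 xlab = "measurement session", ylab = series$label,
                 ylim = range(series$values, limits$lower, limits$upper),
                 main = sprintf("Constancy check: %s", series$label))
  graphics::abline(h = limits$mean, lty = 1)
  graphics::abline(h = c(limits$lower, limits$upper), lty = 2)
  if (any(flags))
    graphics::points(which(flags), series$values[flags], pch = 4, cex = 2,
                     col = "red")
  invisible(limits)
}
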