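#' Dose-rate indices of an acquisition
#'
#' `k_rate` is the incident air kerma rate at the phantom entrance surface
#' (uGy/s); `pka_rate` is the air kerma-area-product rate (uGy.m^2/s) read
#' by a transmission (KAP) chamber.  Uncertainties are stored at coverage
#' factor k = 1 (1 SD); instrument calibrations quoted at k = 2 must be
#' declared via `coverage_factor = 2` and are halved on entry.
#'
#' @param k_rate Air kerma rate in uGy/s (> 0).
#' @param pka_rate Kerma-area-product rate in uGy.m^2/s (> 0).
#' @param sigma_rel_dose Relative uncertainty of the dose indices
#'   (fraction, >= 0), at the stated coverage factor.
#' @param coverage_factor Coverage factor of `sigma_rel_dose` (1 or 2).
#' @return Object of class `dose_indices` (uncertainty stored at k = 1).
#' @export
dose_indices <- function(k_rate, pka_rate, sigma_rel_dose = 0,
                         coverage_factor = 1) {
  if (!is_number(k_rate) || k_rate <= 0) stopf("k_rate must be > 0 (uGy/s)")
  if (!is_number(pka_rate) || pka_rate <= 0)
    stopf("pka_rate must be > 0 (uGy.m^2/s)")
  if (!is_number(sigma_rel_dose) || sigma_rel_dose < 0)
    stopf("sigma_rel_dose must be >= 0")
  if (!coverage_factor %in% c(1, 2))
    stopf("coverage_factor must be 1 or 2")
  structure(list(k_rate = k_rate, pka_rate = pka_rate,
                 sigma_rel_dose = sigma_rel_dose / coverage_factor,
                 units = c(k_rate = "uGy/s", pka_rate = "uGy.m^2/s")),
            class = "dose_indices")
}

#' Dose-normalised figures of merit (dose efficiency)
#'
#' `FOM_K = SNR2_rate / K_rate` (uGy^-1) and
#' `FOM_KA = SNR2_rate / P_KA,rate` (uGy^-1.m^-2): image-quality rate per
#' unit dose rate.  The relative FOM uncertainties combine the SNR-rate and
#' dose uncertainties in quadrature ([fom_sigma()]), treating the two as
#' independent.
#'
#' @param snr An [snr_result()] or a plain non-negative `SNR2_rate` (s^-1).
#' @param dose A [dose_indices()] object; plain numbers are rejected so
#'   units are always declared.
#' @param sigma_rel_snr Relative uncertainty of `SNR2_rate`; defaults to
#'   the `sigma_stat_rel` carried by `snr` (0 for a plain number).
#' @return Object of class `fom_result` with `fom_k`, `fom_ka`,
#'   `sigma_rel_fom_k`, `sigma_rel_fom_ka` and a `units` field.
#' @export
compute_fom <- function(snr, dose, sigma_rel_snr = NULL) {
  if (inherits(snr, "snr_result")) {
    snr2_rate <- snr$snr2_rate
    if (is.null(sigma_rel_snr)) sigma_rel_snr <- snr$sigma_stat_rel
  } else {
    if (!is_number(snr) || snr < 0) stopf("snr must be >= 0 (s^-1)")
    snr2_rate <- snr
    if (is.null(sigma_rel_snr)) sigma_rel_snr <- 0
  }
  if (!inherits(dose, "dose_indices"))
    stopf("dose must be a dose_indices object (units must be declared)")
  s <- fom_sigma(sigma_rel_snr, dose$sigma_rel_dose)
  structure(list(fom_k = snr2_rate / dose$k_rate,
                 fom_ka = snr2_rate / dose$pka_rate,
                 sigma_rel_fom_k = s, sigma_rel_fom_ka = s,
                 units = c(fom_k = "uGy^-1", fom_ka = "uGy^-1.m^-2")),
            class = "fom_result")
}

#' @export
print.fom_result <- function(x, ...) {
  cat(sprintf("fom_result: FOM_K = %.4g uGy^-1 (+/- %.1f%%), FOM_KA = %.4g uGy^-1.m^-2 (+/- %.1f%%)\n",
              x$fom_k, 100 * x$sigma_rel_fom_k,
              x$fom_ka, 100 * x$sigma_rel_fom_ka))
  invisible(x)
}

#' One systematic term of the SNR-rate uncertainty budget
#'
#' A setup parameter X (dose index D, squared magnification M^2, field size
#' FS, ...) that varies between experiments contributes
#' `B_X * X * sigma_rel_X` to the SNR-rate uncertainty, where `B_X` is the
#' slope of the linear relation of `SNR2_rate` with X and the product is
#' expressed relative to `SNR2_rate`.  With the defaults
#' (`b_slope = x_value = 1`) the contribution is simply `sigma_rel`, for
#' budgets quoted directly as relative contributions.  Slopes are
#' instrument-specific and must be supplied by the user; they are never
#' invented by the package.
#'
#' @param name Term label (e.g. `"D"`, `"M2"`, `"FS"`).
#' @param sigma_rel Relative uncertainty of X (fraction >= 0, k = 1).
#' @param b_slope Slope B_X of `SNR2_rate` versus X, relative units.
#' @param x_value Current value of X.
#' @return Object of class `uncertainty_term`.
#' @export
uncertainty_term <- function(name, sigma_rel, b_slope = 1, x_value = 1) {
  if (!is_number(sigma_rel) || sigma_rel < 0) stopf("sigma_rel must be >= 0")
  if (!is_number(b_slope) || !is_number(x_value))
    stopf("b_slope and x_value must be numbers")
  if (b_slope * x_value < 0) stopf("B_X * X must be >= 0")
  structure(list(name = as.character(name), sigma_rel = sigma_rel,
                 b_slope = b_slope, x_value = x_value,
                 contribution = b_slope * x_value * sigma_rel),
            class = "uncertainty_term")
}

#' Uncertainty budget for an SNR-rate measurement
#'
#' @param sigma_stat Relative statistical uncertainty (fraction >= 0).
#' @param terms List of [uncertainty_term()]s (default none, so the budget
#'   degenerates to `sigma_stat`).
#' @return Object of class `uncertainty_budget`.
#' @export
uncertainty_budget <- function(sigma_stat, terms = list()) {
  if (!is_number(sigma_stat) || sigma_stat < 0)
    stopf("sigma_stat must be >= 0")
  if (!all(vapply(terms, inherits, TRUE, "uncertainty_term")))
    stopf("terms must be uncertainty_term objects")
  structure(list(sigma_stat = sigma_stat, terms = terms),
            class = "uncertainty_budget")
}

#' Combined relative uncertainty of SNR^2 rate
#'
#' Root-sum-square of the statistical term and every systematic term:
#' `sigma_SNR2rate = sqrt(sigma_stat^2 + sum_X (B_X * X * sigma_rel_X)^2)`,
#' all expressed relative to `SNR2_rate`.
#'
#' @param budget An [uncertainty_budget()].
#' @return Combined relative uncertainty (fraction).
#' @export
combined_uncertainty <- function(budget) {
  if (!inherits(budget, "uncertainty_budget"))
    stopf("budget must be an uncertainty_budget")
  contrib <- vapply(budget$terms, function(t) t$contribution, 0)
  if (any(contrib < 0)) stopf("negative uncertainty contribution")
  sqrt(budget$sigma_stat^2 + sum(contrib^2))
}

#' Relative uncertainty of a figure of merit
#'
#' SNR^2 rate and the dose index are treated as independent, so their
#' relative uncertainties add in quadrature:
#' `sigma_FOM = sqrt(sigma_rel_snr^2 + sigma_rel_dose^2)`.
#'
#' @param sigma_rel_snr Relative uncertainty of SNR2_rate (>= 0).
#' @param sigma_rel_dose Relative uncertainty of the dose index (>= 0).
#' @return Relative FOM uncertainty (fraction).
#' @export
fom_sigma <- function(sigma_rel_snr, sigma_rel_dose) {
  if (!is_number(sigma_rel_snr) || sigma_rel_snr < 0 ||
      !is_number(sigma_rel_dose) || sigma_rel_dose < 0)
    stopf("uncertainties must be >= 0")
  sqrt(sigma_rel_snr^2 + sigma_rel_dose^2)
}
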