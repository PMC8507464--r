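#' Example figure-of-merit measurement table
#'
#' Published session measurements from a fixed-geometry clinical
#' fluoroscopy study of x-ray field-size dependence (20 cm attenuating
#' phantom, 81 kV, 0.3 mm Cu filtration, low-density 15 mm contrast
#' detail): measured `SNR2_rate`, the two dose-rate indices, and the
#' figures of merit printed alongside them.  Used to demonstrate and test
#' the FOM arithmetic — dividing the printed `SNR2_rate` column by each
#' printed dose column reproduces the printed FOM columns to within their
#' rounding.
#'
#' @return Data frame with columns `field_size_cm2`, `snr2_rate_per_s`,
#'   `k_rate_uGy_s`, `pka_rate_uGy_m2_s`, `fom_k_per_uGy`,
#'   `fom_ka_per_uGy_m2`.
#' @export
example_fom_table <- function() {
  read.csv(system.file("extdata", "fom_sessions_table.csv",
                       package = "fluorosnr", mustWork = TRUE))
}
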