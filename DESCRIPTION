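Package: fluorosnr
Title: Model-Observer Detectability Rate and Dose-Efficiency QC for
    Fluoroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Objective low-contrast detectability measurement for pulsed
    fluoroscopy frame sequences using a quasi-ideal (DC- and optionally
    high-frequency-suppressing) model observer.  Builds a matched-filter
    template from signal-present and signal-absent frame stacks, scores
    each frame to a conditional decision variable with leave-one-out bias
    control, and estimates the single-frame squared signal-to-noise ratio
    SNR2_sf, the lag factor F (effective independent frames per second),
    and the detectability rate SNR2_rate = SNR2_sf * F.  Provides
    dose-normalised figures of merit against air kerma rate and
    kerma-area-product rate, a combined uncertainty budget, moving-block
    bootstrap statistical uncertainties, control-chart trending for
    constancy checks, and a synthetic contrast-detail phantom simulator
    with analytic Rose-model oracles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
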