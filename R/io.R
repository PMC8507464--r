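#' Write a frame stack to disk
#'
#' Two portable formats:
#' * `raw` — little-endian float64 pixel data (column-major, frame by
#'   frame) plus a JSON sidecar `<path>.json` holding shape, dtype and
#'   frame rate;
#' * `tiff` — multi-page 16-bit TIFF (pixel values rounded to integers in
#'   0..65535), with the same JSON sidecar carrying the frame rate, since
#'   baseline TIFF has no frame-time metadata.
#'
#' @param stack A [frame_stack()].
#' @param path Output file path.
#' @param format `"raw"` or `"tiff"`; inferred from the extension when
#'   missing (`.tif`/`.tiff` vs anything else).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, format = NULL) {
  if (!inherits(stack, "frame_stack")) stopf("stack must be a frame_stack")
  format <- .stack_format(path, format)
  d <- dim(stack$pixels)
  sidecar <- list(format = format, rows = d[1], cols = d[2], n_frames = d[3],
                  dtype = "float64", byte_order = "little",
                  frame_rate_fp = stack$frame_rate_fp,
                  pixel_pitch_mm = stack$pixel_pitch_mm,
                  provenance = stack$provenance)
  if (format == "raw") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(stack$pixels), con, size = 8, endian = "little")
  } else {
    vals <- round(stack$pixels)
    if (min(vals) < 0 || max(vals) > 65535)
      stopf("pixel values outside 0..65535 cannot be stored as 16-bit TIFF")
    pages <- lapply(seq_len(d[3]), function(i) vals[, , i] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    sidecar$dtype <- "uint16"
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.stack_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("raw", "tiff")))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "raw"
}

#' Read a frame stack from disk
#'
#' Reads the formats written by [write_stack()].  The frame rate is
#' essential for the lag factor and is never guessed: precedence is the
#' `frame_rate_fp` argument (config/CLI override), then the JSON sidecar,
#' then an error.  Truncated raw files are rejected with the offending
#' byte/frame position.
#'
#' @param path Stack file path.
#' @param format `"raw"` or `"tiff"` (inferred from the extension when
#'   missing).
#' @param frame_rate_fp Optional frame-rate override in s^-1.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, format = NULL, frame_rate_fp = NULL) {
  if (!file.exists(path)) stopf("stack file not found: %s", path)
  format <- .stack_format(path, format)
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path))
    jsonlite::fromJSON(sidecar_path) else NULL
  fp <- frame_rate_fp
  if (is.null(fp)) fp <- sidecar$frame_rate_fp
  if (is.null(fp))
    stopf("no frame rate: pass frame_rate_fp or provide the JSON sidecar %s",
          sidecar_path)
  if (format == "raw") {
    if (is.null(sidecar))
      stopf("raw stack requires the JSON sidecar %s", sidecar_path)
    n_pix <- sidecar$rows * sidecar$cols * sidecar$n_frames
    expected <- 8 * n_pix
    actual <- file.size(path)
    if (actual != expected)
      stopf("truncated/corrupt raw stack %s: expected %d bytes (%d frames), got %d (ends inside frame %d)",
            path, expected, sidecar$n_frames, actual,
            floor(actual / (8 * sidecar$rows * sidecar$cols)) + 1)
    con <- file(path, "rb")
    on.exit(close(con))
    pix <- readBin(con, "double", n = n_pix, size = 8, endian = "little")
    arr <- array(pix, dim = c(sidecar$rows, sidecar$cols, sidecar$n_frames))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L)
      stopf("%s holds a single 2-D image; a stack needs >= 2 frames", path)
    arr <- array(unlist(lapply(pages, function(p) round(p * 65535)),
                        use.names = FALSE),
                 dim = c(dim(pages[[1]])[1:2], length(pages)))
  }
  frame_stack(arr, fp,
              pixel_pitch_mm = sidecar$pixel_pitch_mm,
              provenance = if (!is.null(sidecar$provenance))
                sidecar$provenance else path)
}

#' Read a configuration file (YAML or JSON)
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Write a configuration list (YAML or JSON, by extension)
#'
#' @param x Named list (e.g. a [sim_config()]).
#' @param path Output path ending in `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_config <- function(x, path) {
  x <- unclass(x)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            null = "null")
  invisible(path)
}

#' Rebuild a simulation config from a plain list
#'
#' Round-trip companion of [write_config()]: validates the list through
#' [sim_config()].
#'
#' @param x Named list with `sim_config` fields.
#' @return A [sim_config()].
#' @export
as_sim_config <- function(x) {
  keep <- intersect(names(x),
                    c("n_frames", "rows", "cols", "N0", "C",
                      "detail_diameter_px", "M", "psf_sigma_px", "ar1_alpha",
                      "frame_rate_fp", "seed", "center"))
  do.call(sim_config, x[keep])
}

# Flatten an snr_result / fom_result / config into one named numeric-ish list.
.flatten_report <- function(snr = NULL, fom = NULL, config = NULL,
                            seed = NULL) {
  out <- list(software = "fluorosnr",
              version = as.character(packageVersion("fluorosnr")))
  if (!is.null(seed)) out$seed <- seed
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg <- cfg[!vapply(cfg, is.null, TRUE)]
    if (length(cfg)) {
      names(cfg) <- paste0("config.", names(cfg))
      out <- c(out, cfg)
    }
  }
  if (!is.null(snr)) {
    if (!inherits(snr, "snr_result")) stopf("snr must be an snr_result")
    out <- c(out, list(snr2_sf = snr$snr2_sf,
                       lag_F_per_s = snr$lag_F,
                       snr2_rate_per_s = snr$snr2_rate,
                       sigma_stat_rel = snr$sigma_stat_rel,
                       n_frames_used = snr$n_frames_used))
  }
  if (!is.null(fom)) {
    if (!inherits(fom, "fom_result")) stopf("fom must be a fom_result")
    out <- c(out, list(fom_k_per_uGy = fom$fom_k,
                       fom_ka_per_uGy_m2 = fom$fom_ka,
                       sigma_rel_fom_k = fom$sigma_rel_fom_k,
                       sigma_rel_fom_ka = fom$sigma_rel_fom_ka))
  }
  out
}

#' Write a measurement report
#'
#' Self-sufficient record of a run: software version, seed, the full input
#' configuration, and every output with units in its field name.  JSON
#' preserves full double precision; the CSV emission is a two-column
#' `field,value` table.  A report can be re-read with [read_report()] and
#' reproduces the numbers bit-for-bit (JSON) for determinism checks.
#'
#' @param snr An [snr_result()] (optional).
#' @param fom A [compute_fom()] result (optional).
#' @param config Input configuration list/[sim_config()] to echo (optional).
#' @param seed Seed used for the run (optional).
#' @param path Output path.
#' @param format `"json"` or `"csv"`; inferred from the extension when
#'   missing.
#' @return `path`, invisibly.
#' @export
write_report <- function(snr = NULL, fom = NULL, config = NULL, seed = NULL,
                         path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  format <- match.arg(format, c("json", "csv"))
  flat <- .flatten_report(snr = snr, fom = fom, config = config, seed = seed)
  if (format == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    rows <- data.frame(
      field = rep(names(flat), lengths(flat)),
      value = vapply(unlist(flat, use.names = FALSE), function(v)
        if (is.numeric(v)) sprintf("%.17g", v) else as.character(v), ""),
      stringsAsFactors = FALSE)
    write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a measurement report back as a named list
#'
#' Values that parse as numbers are returned numeric, so JSON and CSV
#' emissions of the same result compare field by field.
#'
#' @param path Report path (`.json` or `.csv`).
#' @return Named list of report fields.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stopf("report not found: %s", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    rows <- read.csv(path, stringsAsFactors = FALSE,
                     colClasses = c("character", "character"))
    vals <- lapply(rows$value, function(v) {
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    })
    # re-assemble multi-entry fields (e.g. config.center) into vectors
    out <- tapply(vals, factor(rows$field, levels = unique(rows$field)),
                  function(v) unlist(v, use.names = FALSE), simplify = FALSE)
    lapply(out, identity)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}
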