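# Readers/writers for the raw ADC cube layout, cohort/feature CSVs and
# JSON reports. Cube layout: little-endian interleaved I/Q 16-bit
# integers, frames-major, with a JSON sidecar carrying the radar
# configuration and the integer scale factor.

#' Write / read a raw IF cube
#'
#' `write_if_cube()` stores the complex samples as little-endian
#' interleaved I/Q int16, frames-major, at `<path>.bin`, plus a JSON
#' sidecar `<path>.json` holding the [radar_config()], the quantization
#' scale, the DC offset and SNR metadata. `read_if_cube()` reverses it
#' and validates the file size against the configured dimensions.
#'
#' @param cube An `if_frame_cube`.
#' @param path Path stem (no extension).
#' @param scale Integer full-scale target; the quantization step is the
#'   power of two `2^ceiling(log2(max(|I|, |Q|) / scale))`, giving about
#'   15 bits of dynamic range. Integer-grid payloads within int16 range
#'   round-trip bit-identically.
#' @return `write_if_cube()`: `path` invisibly. `read_if_cube()`: an
#'   `if_frame_cube`.
#' @export
write_if_cube <- function(cube, path, scale = 32000L) {
  stopifnot(inherits(cube, "if_frame_cube"))
  s <- cube$samples
  peak <- max(abs(Re(s)), abs(Im(s)), 1e-300)
  # power-of-two quantization step: scaling is exact in binary floating
  # point, so integer-grid payloads survive the round trip bit-identically
  scale_factor <- 2^ceiling(log2(peak / scale))
  iq <- rbind(as.vector(t(Re(s))), as.vector(t(Im(s))))  # interleave I,Q
  ints <- as.integer(round(iq / scale_factor))
  writeBin(ints, paste0(path, ".bin"), size = 2L, endian = "little")
  sidecar <- list(
    format = "radarbp-if-cube-v1",
    config = unclass(cube$config)[c("carrier_frequency_ghz",
                                    "chirp_slope_mhz_us",
                                    "adc_sample_rate_mhz",
                                    "adc_samples_per_chirp",
                                    "frame_period_ms", "n_frames",
                                    "pulse_duration_us")],
    scale_factor = scale_factor,
    dc_offset = c(Re(cube$dc_offset), Im(cube$dc_offset)),
    noise_snr_db = if (is.finite(cube$noise_snr_db))
      cube$noise_snr_db else "Inf",
    time_origin_s = 0)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_if_cube
#' @export
read_if_cube <- function(path) {
  side_path <- paste0(path, ".json")
  bin_path <- paste0(path, ".bin")
  if (!file.exists(side_path) || !file.exists(bin_path)) {
    stop(sprintf("cube files not found at stem '%s'", path), call. = FALSE)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  config <- do.call(radar_config, side$config)
  expected <- 2L * config$n_frames * config$adc_samples_per_chirp
  actual <- file.size(bin_path) / 2
  if (actual != expected) {
    stop(sprintf(paste0("shape mismatch: config implies %d int16 samples ",
                        "(%d frames x %d fast-time x I/Q) but file holds %d"),
                 expected, config$n_frames, config$adc_samples_per_chirp,
                 as.integer(actual)), call. = FALSE)
  }
  ints <- readBin(bin_path, integer(), n = expected, size = 2L,
                  signed = TRUE, endian = "little")
  vals <- ints * side$scale_factor
  i_part <- vals[seq(1, expected, by = 2)]
  q_part <- vals[seq(2, expected, by = 2)]
  samples <- matrix(complex(real = i_part, imaginary = q_part),
                    nrow = config$n_frames,
                    ncol = config$adc_samples_per_chirp, byrow = TRUE)
  snr <- side$noise_snr_db
  snr <- if (identical(snr, "Inf")) Inf else as.numeric(snr)
  structure(list(samples = samples, config = config,
                 dc_offset = complex(real = side$dc_offset[1],
                                     imaginary = side$dc_offset[2]),
                 noise_snr_db = snr, target_range_m = NA_real_),
            class = "if_frame_cube")
}

#' Write / read a cohort readings table
#'
#' CSV with fixed, unit-suffixed columns (`sbp_mmhg`, `ptt_s`, ...).
#'
#' @param cohort A [generate_cohort()] result.
#' @param path CSV path.
#' @return `write_cohort_csv()`: `path` invisibly; `read_features_csv()`
#'   / `read_cohort_csv()`: data frames.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  utils::write.csv(cohort$readings, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) utils::read.csv(path)

#' @rdname write_cohort_csv
#' @param features Feature data frame ([cohort_features()] layout).
#' @export
write_features_csv <- function(features, path) {
  stopifnot(is.data.frame(features))
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("pwv_mps", "auc_s", "sbp_mmhg", "dbp_mmhg")
  if (!all(need %in% names(df))) {
    stop(sprintf("feature CSV missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Write an evaluation report as JSON
#'
#' @param report An [evaluate_models()] result.
#' @param path JSON path.
#' @return `path` invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

# ---- run manifest ----------------------------------------------------

# Deterministic manifest: config hash, package version, per-file md5
# checksums, and every warning emitted by the run. No timestamps, so
# repeated runs of a seeded pipeline produce byte-identical manifests.
build_manifest <- function(stage, config, inputs = character(0),
                           outputs = character(0), warnings = character(0)) {
  hash_of <- function(obj) {
    tmp <- tempfile()
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA)
    unname(tools::md5sum(tmp))
  }
  checksums <- function(paths) {
    existing <- paths[file.exists(paths)]
    stats::setNames(as.list(unname(tools::md5sum(existing))),
                    basename(existing))
  }
  list(stage = stage,
       software = paste0("radarbp ",
                         as.character(utils::packageVersion("radarbp"))),
       config_hash = hash_of(config),
       inputs = checksums(inputs),
       outputs = checksums(outputs),
       warnings = as.list(warnings))
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
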