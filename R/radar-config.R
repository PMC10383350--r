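# Radar chirp/frame parameterisation. Defaults follow a 77 GHz automotive
# FMCW evaluation board configured for vital-sign capture: 0.5 ms frame
# period (2 kHz slow-time rate), 128 ADC samples per chirp, 10 s records.

#' FMCW radar configuration
#'
#' Chirp and frame parameters defining fast-time sampling, slow-time
#' sampling and carrier wavelength.
#'
#' @param carrier_frequency_ghz Carrier frequency (GHz). The chest radar
#'   runs at 77 GHz and the wrist radar at 79 GHz so the two do not
#'   interfere.
#' @param chirp_slope_mhz_us Chirp slope (MHz/microsecond).
#' @param adc_sample_rate_mhz Fast-time ADC sample rate (MHz).
#' @param adc_samples_per_chirp Number of complex fast-time samples.
#' @param frame_period_ms Frame (chirp repetition) period (ms); this is
#'   the slow-time sampling period of the displacement readout.
#' @param n_frames Number of frames in one record.
#' @param pulse_duration_us Chirp duration (microseconds); must cover the
#'   ADC acquisition window.
#' @return An object of class `radar_config` with derived fields
#'   `wavelength_m` and `bin_spacing_m`.
#' @export
#' @examples
#' cfg <- radar_config()                     # chest radar, 10 s record
#' cfg$wavelength_m * 1e3                    # ~3.89 mm
radar_config <- function(carrier_frequency_ghz = 77,
                         chirp_slope_mhz_us = 29.99,
                         adc_sample_rate_mhz = 2.5,
                         adc_samples_per_chirp = 128,
                         frame_period_ms = 0.5,
                         n_frames = 20000,
                         pulse_duration_us = 57) {
  stopifnot_positive(carrier_frequency_ghz = carrier_frequency_ghz,
                     chirp_slope_mhz_us = chirp_slope_mhz_us,
                     adc_sample_rate_mhz = adc_sample_rate_mhz,
                     frame_period_ms = frame_period_ms,
                     pulse_duration_us = pulse_duration_us)
  stopifnot(adc_samples_per_chirp >= 2, n_frames >= 1)
  acq_us <- adc_samples_per_chirp / adc_sample_rate_mhz
  if (acq_us > pulse_duration_us) {
    stop(sprintf(paste0("ADC acquisition window (%.1f us) exceeds the ",
                        "chirp duration (%.1f us)"),
         acq_us, pulse_duration_us), call. = FALSE)
  }
  fc <- carrier_frequency_ghz * 1e9
  slope <- chirp_slope_mhz_us * 1e12          # Hz/s
  fs <- adc_sample_rate_mhz * 1e6             # Hz
  cfg <- list(carrier_frequency_ghz = carrier_frequency_ghz,
              chirp_slope_mhz_us = chirp_slope_mhz_us,
              adc_sample_rate_mhz = adc_sample_rate_mhz,
              adc_samples_per_chirp = as.integer(adc_samples_per_chirp),
              frame_period_ms = frame_period_ms,
              n_frames = as.integer(n_frames),
              pulse_duration_us = pulse_duration_us,
              wavelength_m = C_LIGHT / fc,
              # one FFT bin (no padding) in range units
              bin_spacing_m = C_LIGHT * (fs / adc_samples_per_chirp) /
                (2 * slope))
  structure(cfg, class = "radar_config")
}

#' @export
print.radar_config <- function(x, ...) {
  cat(sprintf(
    "<radar_config> %g GHz, slope %g MHz/us, %d samples @ %g MHz\n",
    x$carrier_frequency_ghz, x$chirp_slope_mhz_us,
    x$adc_samples_per_chirp, x$adc_sample_rate_mhz))
  cat(sprintf("  %d frames @ %g ms (%.2f s record), wavelength %.3f mm, bin %.3f m\n",
              x$n_frames, x$frame_period_ms,
              x$n_frames * x$frame_period_ms / 1e3,
              x$wavelength_m * 1e3, x$bin_spacing_m))
  invisible(x)
}

# Maximum unambiguous range of the de-chirped signal (fs/2 beat limit).
max_range <- function(config) {
  fs <- config$adc_sample_rate_mhz * 1e6
  slope <- config$chirp_slope_mhz_us * 1e12
  C_LIGHT * fs / (4 * slope)
}

# Beat frequency (Hz) of a point target at range r.
beat_frequency <- function(r, config) {
  2 * r * config$chirp_slope_mhz_us * 1e12 / C_LIGHT
}
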