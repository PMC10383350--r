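# Synthetic measurement generator: ground-truth skin displacement for
# chest and wrist, and the corresponding raw FMCW intermediate-frequency
# (IF) frame cubes, so the whole signal chain is testable without
# human-subject recordings.

#' Pulse waveform model
#'
#' Parametric model of the skin-displacement waveform at one body site:
#' a train of raised-cosine systolic peaks at the heart rate, optionally
#' superposed on a respiration sinusoid (chest only), and delayed by the
#' pulse transit time (wrist only). Raised-cosine peaks are used because
#' the area-under-curve sharpness feature of a single peak then has the
#' closed form `B / (2 * pi)` (B = peak width), giving an analytic oracle
#' for tests; no dicrotic notch is modelled since the radar readout
#' resolves only the systolic peak.
#'
#' @param heart_rate_hz Heart rate (Hz); default 1.2 Hz (72 bpm).
#' @param pulse_amplitude_mm Peak displacement of one systolic pulse (mm),
#'   in `[0.01, 1]` (or 0 for a null model). Defaults: chest 0.3 mm;
#'   use ~0.08 mm for the wrist, where the pulse is much weaker.
#' @param pulse_width_s Full width of one raised-cosine peak (s); must be
#'   shorter than the beat interval.
#' @param respiration_amplitude_mm Respiration displacement amplitude
#'   (mm); chest only, must be 0 for the wrist site.
#' @param respiration_rate_hz Respiration rate (Hz).
#' @param ptt_delay_s Pulse transit delay applied to the train (s); wrist
#'   only.
#' @return An object of class `pulse_waveform_model`.
#' @export
pulse_waveform_model <- function(heart_rate_hz = 1.2,
                                 pulse_amplitude_mm = 0.3,
                                 pulse_width_s = 0.25,
                                 respiration_amplitude_mm = 0,
                                 respiration_rate_hz = 0.25,
                                 ptt_delay_s = 0) {
  stopifnot(heart_rate_hz > 0,
            pulse_amplitude_mm == 0 ||
              (pulse_amplitude_mm >= 0.01 && pulse_amplitude_mm <= 1),
            respiration_amplitude_mm >= 0, respiration_rate_hz > 0,
            ptt_delay_s >= 0)
  if (pulse_width_s >= 1 / heart_rate_hz) {
    stop("`pulse_width_s` must be shorter than the beat interval",
         call. = FALSE)
  }
  structure(list(heart_rate_hz = heart_rate_hz,
                 pulse_amplitude_mm = pulse_amplitude_mm,
                 pulse_width_s = pulse_width_s,
                 respiration_amplitude_mm = respiration_amplitude_mm,
                 respiration_rate_hz = respiration_rate_hz,
                 ptt_delay_s = ptt_delay_s),
            class = "pulse_waveform_model")
}

#' Generate a ground-truth displacement trace
#'
#' Samples the waveform model at the radar frame period for the length of
#' the configured record: raised-cosine peaks
#' `A/2 * (1 + cos(2*pi*(t - t_k)/B))` on `|t - t_k| <= B/2` centred at
#' `t_k = ptt_delay + (k + 1/2) / heart_rate` (the half-beat offset keeps
#' the first systole clear of the record start, so an N-second record at
#' heart rate f holds exactly `N * f` whole peaks), plus the respiration
#' sinusoid. Peaks whose support intersects the record are included, so a
#' delayed trace is (up to record edges) a pure shift of the undelayed
#' one.
#'
#' @param model A [pulse_waveform_model()].
#' @param config A [radar_config()] supplying `frame_period_ms` and
#'   `n_frames`.
#' @param radar_id Label stored on the trace.
#' @return A [displacement_trace()] (mm).
#' @export
#' @examples
#' cfg <- radar_config(n_frames = 4000)
#' tr <- generate_displacement(pulse_waveform_model(heart_rate_hz = 1), cfg)
generate_displacement <- function(model, config, radar_id = NA_character_) {
  stopifnot(inherits(model, "pulse_waveform_model"),
            inherits(config, "radar_config"))
  dt <- config$frame_period_ms / 1e3
  t <- (seq_len(config$n_frames) - 1) * dt
  d <- numeric(length(t))
  if (model$pulse_amplitude_mm > 0) {
    B <- model$pulse_width_s
    beat <- 1 / model$heart_rate_hz
    t_end <- t[length(t)]
    k <- seq(floor((-B / 2 - model$ptt_delay_s) / beat - 0.5),
             ceiling((t_end + B / 2 - model$ptt_delay_s) / beat))
    centers <- model$ptt_delay_s + (k + 0.5) * beat
    for (tc in centers) {
      idx <- which(abs(t - tc) <= B / 2)
      if (length(idx)) {
        d[idx] <- d[idx] + model$pulse_amplitude_mm * 0.5 *
          (1 + cos(2 * pi * (t[idx] - tc) / B))
      }
    }
  }
  if (model$respiration_amplitude_mm > 0) {
    d <- d + model$respiration_amplitude_mm *
      sin(2 * pi * model$respiration_rate_hz * t)
  }
  displacement_trace(d, sample_period_s = dt, radar_id = radar_id)
}

#' Synthesize a raw FMCW IF frame cube from a displacement trace
#'
#' Builds the de-chirped (intermediate-frequency) complex baseband record
#' a radar would produce for a single point target at `target_range_m`
#' whose range is modulated by the skin displacement `d(t)`. Per frame
#' `m`, the fast-time samples are a unit tone at the target's beat
#' frequency with slow-time phase `4*pi*(R + d(t_m)) / lambda`, plus a
#' constant complex DC offset and, if `snr_db` is finite, circular
#' complex Gaussian noise at the requested per-sample SNR.
#'
#' @param trace A [displacement_trace()] (mm); its length must equal
#'   `config$n_frames`.
#' @param config A [radar_config()].
#' @param target_range_m Standoff distance radar-to-skin (m); default the
#'   0.5 m measurement geometry. Must be within the unambiguous range.
#' @param dc_offset Complex DC offset added to every sample.
#' @param snr_db Per-sample signal-to-noise ratio (dB); `Inf` for
#'   noiseless.
#' @param seed Integer seed for the noise draw (reproducible).
#' @return An object of class `if_frame_cube` with fields `samples`
#'   (complex `n_frames x adc_samples_per_chirp` matrix), `config`,
#'   `dc_offset`, `noise_snr_db`.
#' @export
synthesize_if_cube <- function(trace, config, target_range_m = 0.5,
                               dc_offset = 0 + 0i, snr_db = Inf,
                               seed = 1L) {
  stopifnot(inherits(trace, "displacement_trace"),
            inherits(config, "radar_config"),
            length(trace$values) == config$n_frames)
  if (target_range_m <= 0 || target_range_m >= max_range(config)) {
    stop(sprintf("`target_range_m` must lie in (0, %.2f m) for this config",
                 max_range(config)), call. = FALSE)
  }
  fs <- config$adc_sample_rate_mhz * 1e6
  n_fast <- config$adc_samples_per_chirp
  fb <- beat_frequency(target_range_m, config)
  lambda <- config$wavelength_m
  # slow-time phase from range + displacement (trace is in mm)
  phi <- 4 * pi * (target_range_m + trace$values * 1e-3) / lambda
  fast <- exp(2i * pi * fb * (seq_len(n_fast) - 1) / fs)   # beat tone
  samples <- exp(1i * phi) %o% fast                        # frames x fast
  if (is.finite(snr_db)) {
    sigma <- sqrt(10^(-snr_db / 10) / 2)  # unit signal amplitude
    noise <- with_seed(seed, {
      complex(real = stats::rnorm(length(samples), sd = sigma),
              imaginary = stats::rnorm(length(samples), sd = sigma))
    })
    samples <- samples + matrix(noise, nrow = nrow(samples))
  }
  samples <- samples + dc_offset
  structure(list(samples = samples, config = config,
                 dc_offset = dc_offset, noise_snr_db = snr_db,
                 target_range_m = target_range_m),
            class = "if_frame_cube")
}

#' @export
print.if_frame_cube <- function(x, ...) {
  cat(sprintf("<if_frame_cube> %d frames x %d fast-time samples, SNR %s dB\n",
              nrow(x$samples), ncol(x$samples),
              ifelse(is.finite(x$noise_snr_db),
                     format(x$noise_snr_db), "Inf")))
  invisible(x)
}
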