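# Shared fixtures: small radar configs and trace builders so most unit
# tests stay well under a second.

small_config <- function(n_frames = 4000, ...) {
  radar_config(n_frames = n_frames, ...)
}

# Raised-cosine single peak on a flat baseline, sampled at dt.
one_peak_trace <- function(B = 0.2, dt = 5e-4, total = 3, center = NULL,
                           amplitude = 1, baseline = 0) {
  t <- seq(0, total, by = dt)
  center <- center %||% (total / 2)
  x <- ifelse(abs(t - center) <= B / 2,
              amplitude * 0.5 * (1 + cos(2 * pi * (t - center) / B)),
              0) + baseline
  displacement_trace(x, dt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Additive white Gaussian noise at a target SNR (dB) relative to the
# trace's signal power.
add_noise_snr <- function(trace, snr_db) {
  p_sig <- mean((trace$values - mean(trace$values))^2)
  sigma <- sqrt(p_sig / 10^(snr_db / 10))
  displacement_trace(trace$values + rnorm(length(trace$values), sd = sigma),
                     trace$sample_period_s, radar_id = trace$radar_id)
}
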