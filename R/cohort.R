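# Synthetic cohort generator. Emulates a measurement campaign in which
# each subject is read repeatedly under activity conditions chosen to
# move blood pressure around (waking, rest, evening, post-exercise),
# with the PTT-BP link of the hyperbolic relation BP = K1/PTT + K2 as the
# generating mechanism. Peak width shrinks as the systolic-pressure wave
# speed rises (pressure-dependent stiffness sharpens the upstroke), so
# the AUC feature tracks SBP while PTT/PWV tracks DBP - the correlation
# structure a pooled feature-combination regression relies on.

CONDITIONS <- c("morning", "rest", "evening", "post_exercise")

# Condition -> where in the subject's DBP range the draw falls (fractions
# of [low, high]) and a representative heart rate.
CONDITION_DBP_FRAC <- list(morning       = c(0.00, 0.30),
                           rest          = c(0.20, 0.55),
                           evening       = c(0.35, 0.70),
                           post_exercise = c(0.60, 1.00))
CONDITION_HEART_RATE <- c(morning = 1.0, rest = 1.1, evening = 1.15,
                          post_exercise = 1.5)

#' Measurement-noise specification for the cohort generator
#'
#' Standard deviations of the noise sources applied per reading:
#' PTT timing jitter (beat-to-beat variability plus delay-estimation
#' error), pulse-width estimation noise, pulse-pressure physiological
#' scatter, and cuff-observation noise on the recorded SBP/DBP.
#'
#' Defaults are calibrated so that each single feature, fitted per
#' subject, explains blood pressure to roughly 3-4 mmHg - the error
#' level radar PTT/AUC readouts achieve in practice: 10 ms of PTT jitter
#' maps to about 3.2 mmHg of DBP-equivalent noise through the hyperbolic
#' PTT-BP relation, and 6 ms of width noise to about 3.3 mmHg of
#' SBP-equivalent noise through the width-wave-speed link.
#'
#' @param ptt_sd_s PTT jitter (s); default 10 ms.
#' @param width_sd_s Pulse-width noise (s); default 6 ms.
#' @param pp_sd_mmhg Pulse-pressure scatter (mmHg); default 3.
#' @param bp_obs_sd_mmhg Cuff repeatability (mmHg); default 1.5.
#' @return A named list of class `noise_spec`.
#' @export
noise_spec <- function(ptt_sd_s = 0.010, width_sd_s = 0.006,
                       pp_sd_mmhg = 3, bp_obs_sd_mmhg = 1.5) {
  stopifnot(ptt_sd_s >= 0, width_sd_s >= 0, pp_sd_mmhg >= 0,
            bp_obs_sd_mmhg >= 0)
  structure(list(ptt_sd_s = ptt_sd_s, width_sd_s = width_sd_s,
                 pp_sd_mmhg = pp_sd_mmhg,
                 bp_obs_sd_mmhg = bp_obs_sd_mmhg),
            class = "noise_spec")
}

#' @rdname noise_spec
#' @export
zero_noise_spec <- function() noise_spec(0, 0, 0, 0)

#' Default synthetic subjects
#'
#' Five subjects whose age, arm length (heart-to-wrist) and health notes
#' follow the demographic defaults of the emulated campaign: three
#' healthy adults, one hypertensive, and one older medicated subject
#' (hypertension and diabetes) whose diastolic readings vary much more
#' than the others'. Baseline DBP ranges and mid-range pulse pressures
#' are chosen to span normotensive-to-hypertensive readings; each
#' subject's K1/K2 constants are derived from a shared calibration that
#' maps the cohort DBP envelope onto PTT in [0.15, 0.30] s, with small
#' fixed per-subject perturbations so the constants remain
#' subject-dependent.
#'
#' @param n Number of subjects (1-5 from the default table; above 5,
#'   extra subjects recycle the healthy profiles with new ids).
#' @return List of [subject_profile()] objects.
#' @export
default_subjects <- function(n = 5) {
  stopifnot(n >= 1)
  tab <- data.frame(
    subject_id = 1:5,
    age        = c(20, 57, 76, 49, 24),
    arm_length = c(0.725, 0.732, 0.643, 0.685, 0.737),
    dbp_lo     = c(62, 82, 65, 68, 63),
    dbp_hi     = c(80, 98, 105, 86, 81),
    pp_base    = c(45, 55, 60, 48, 44),
    k1_jitter  = c(0.03, -0.04, 0.06, -0.02, 0.01),
    k2_jitter  = c(-1.0, 1.5, -2.0, 0.8, 0.3),
    note = c("healthy", "hypertension",
             "hypertension and diabetes (taking medication)",
             "healthy", "healthy"),
    stringsAsFactors = FALSE)
  env_lo <- min(tab$dbp_lo); env_hi <- max(tab$dbp_hi)
  rows <- ((seq_len(n) - 1) %% 5) + 1
  out <- vector("list", n)
  for (i in seq_len(n)) {
    r <- tab[rows[i], ]
    K1c <- (env_hi - env_lo) / (1 / 0.15 - 1 / 0.30)
    K2c <- env_lo - K1c / 0.30
    params <- bp_model_params(K1 = K1c * (1 + r$k1_jitter),
                              K2 = K2c + r$k2_jitter)
    out[[i]] <- subject_profile(
      subject_id = i, age = r$age, arm_length = r$arm_length,
      bp_params = params,
      baseline_dbp_range = c(r$dbp_lo, r$dbp_hi),
      baseline_sbp_range = c(r$dbp_lo, r$dbp_hi) + r$pp_base,
      pp_base = r$pp_base, note = r$note)
  }
  out
}

#' Generate a synthetic cohort of paired radar/cuff readings
#'
#' Per reading: draw an activity condition, place the true DBP in the
#' condition's portion of the subject's baseline range, draw pulse
#' pressure around the subject's mid-range value (rising with DBP) to
#' obtain SBP, invert the subject's `BP = K1/PTT + K2` relation for the
#' true (diastolic) PTT, and set the systolic peak width as a decreasing
#' function of the systolic-pressure wave speed,
#' `width = width_coeff / PWV_sys` with `PWV_sys = L / ptt_from_bp(SBP)`:
#' the wall is stiffer at the instantaneous systolic pressure, so the
#' upstroke travels faster and the peak sharpens - the AUC feature
#' shrinks - as pressure rises. With zero noise, `1/PTT` is an exact
#' linear image of DBP and AUC a strictly decreasing function of SBP, so
#' the two features carry complementary information. Measurement noise
#' per [noise_spec()] is then applied to the stored PTT, pulse width and
#' cuff pressures.
#'
#' @param n_subjects Number of subjects (default 5).
#' @param readings_per_subject Readings per subject (default 50).
#' @param noise A [noise_spec()]; use [zero_noise_spec()] for an exact
#'   generative link.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of it.
#' @param subjects Optional list of [subject_profile()]s overriding
#'   [default_subjects()].
#' @param width_coeff Pulse-width coefficient (m): `width = width_coeff /
#'   PWV_sys` seconds; default 1.2 m gives widths of roughly 0.14-0.27 s
#'   over the physiological systolic wave-speed band.
#' @return An object of class `synthetic_cohort`: list with `subjects`,
#'   `readings` (data frame: subject_id, condition, sbp_mmhg, dbp_mmhg,
#'   pp_mmhg, ptt_s, pulse_width_s, heart_rate_hz), `rng_seed`, `noise`,
#'   `width_coeff`.
#' @export
#' @examples
#' coh <- generate_cohort(seed = 7)
#' nrow(coh$readings)   # 250
generate_cohort <- function(n_subjects = 5, readings_per_subject = 50,
                            noise = noise_spec(), seed = 1L,
                            subjects = NULL, width_coeff = 1.2) {
  stopifnot(n_subjects >= 1, readings_per_subject >= 1,
            inherits(noise, "noise_spec"), width_coeff > 0)
  subjects <- subjects %||% default_subjects(n_subjects)
  stopifnot(length(subjects) == n_subjects)
  readings <- with_seed(seed, {
    rows <- vector("list", n_subjects * readings_per_subject)
    k <- 0L
    for (s in subjects) {
      lo <- s$baseline_dbp_range[1]; hi <- s$baseline_dbp_range[2]
      mid <- (lo + hi) / 2
      for (j in seq_len(readings_per_subject)) {
        cond <- sample(CONDITIONS, 1L)
        dbp_true <- NA_real_
        for (attempt in 1:20) {  # resample cap for infeasible draws
          fr <- CONDITION_DBP_FRAC[[cond]]
          cand <- lo + stats::runif(1, fr[1], fr[2]) * (hi - lo)
          if (cand > s$bp_params$K2) { dbp_true <- cand; break }
        }
        if (is.na(dbp_true)) {
          stop(sprintf("subject %s: DBP draw never exceeded K2 = %.1f",
                       s$subject_id, s$bp_params$K2), call. = FALSE)
        }
        pp_true <- max(10, s$pp_base + 0.5 * (dbp_true - mid) +
                         stats::rnorm(1, sd = noise$pp_sd_mmhg))
        ptt_true <- ptt_from_bp(dbp_true, s$bp_params)
        ptt <- ptt_true + stats::rnorm(1, sd = noise$ptt_sd_s)
        ptt <- max(ptt, 0.02)
        # systolic-pressure wave speed via the same subject constants:
        # stiffer wall at systole -> faster upstroke -> sharper peak
        pwv_sys <- s$arm_length / ptt_from_bp(dbp_true + pp_true, s$bp_params)
        width <- width_coeff / pwv_sys + stats::rnorm(1, sd = noise$width_sd_s)
        width <- max(width, 0.05)
        dbp_obs <- dbp_true + stats::rnorm(1, sd = noise$bp_obs_sd_mmhg)
        sbp_obs <- dbp_true + pp_true + stats::rnorm(1, sd = noise$bp_obs_sd_mmhg)
        k <- k + 1L
        rows[[k]] <- data.frame(
          subject_id = s$subject_id, condition = cond,
          sbp_mmhg = sbp_obs, dbp_mmhg = dbp_obs,
          pp_mmhg = sbp_obs - dbp_obs,
          ptt_s = ptt, pulse_width_s = width,
          heart_rate_hz = unname(CONDITION_HEART_RATE[cond]),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  if (any(readings$pp_mmhg <= 0)) {
    stop("internal error: non-positive pulse pressure generated",
         call. = FALSE)
  }
  structure(list(subjects = subjects, readings = readings,
                 rng_seed = as.integer(seed), noise = noise,
                 width_coeff = width_coeff),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d readings (seed %d)\n",
              length(x$subjects), nrow(x$readings), x$rng_seed))
  invisible(x)
}

#' Derive the feature table of a synthetic cohort
#'
#' Builds per-reading feature records (PTT, PWV, AUC) from the cohort's
#' stored measurement-level quantities: `pwv = L / ptt` and, for the
#' raised-cosine peak family used by the simulator, the AUC sharpness
#' feature equals `pulse_width / (2 * pi)` in closed form. The
#' equivalence of this closed form with the full radar chain
#' (cube -> displacement -> peak AUC) is exercised by the round-trip
#' tests; using it here keeps cohort-scale evaluation fast.
#'
#' @param cohort A [generate_cohort()] result.
#' @return Data frame with columns `subject_id`, `ptt_s`, `pwv_mps`,
#'   `auc_s`, `sbp_mmhg`, `dbp_mmhg`, `pp_mmhg`.
#' @export
cohort_features <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rd <- cohort$readings
  L <- vapply(cohort$subjects, `[[`, numeric(1), "arm_length")
  names(L) <- vapply(cohort$subjects,
                     function(s) as.character(s$subject_id), character(1))
  arm <- L[as.character(rd$subject_id)]
  data.frame(subject_id = rd$subject_id,
             ptt_s = rd$ptt_s,
             pwv_mps = unname(arm) / rd$ptt_s,
             auc_s = rd$pulse_width_s / (2 * pi),
             sbp_mmhg = rd$sbp_mmhg,
             dbp_mmhg = rd$dbp_mmhg,
             pp_mmhg = rd$pp_mmhg,
             stringsAsFactors = FALSE)
}

#' Waveform models for one cohort reading
#'
#' Maps a cohort reading to the chest and wrist [pulse_waveform_model()]s
#' that the radar-level simulator consumes: chest pulses of 0.3 mm with a
#' respiration component, wrist pulses of 0.08 mm (the wrist pulse is
#' much weaker) delayed by the reading's PTT, both with the reading's
#' pulse width and condition heart rate.
#'
#' @param cohort A [generate_cohort()] result.
#' @param reading Row index into `cohort$readings`.
#' @param chest_amplitude_mm,wrist_amplitude_mm Site pulse amplitudes.
#' @param respiration_amplitude_mm Chest respiration amplitude (mm).
#' @return List with elements `chest` and `wrist`.
#' @export
reading_to_models <- function(cohort, reading,
                              chest_amplitude_mm = 0.3,
                              wrist_amplitude_mm = 0.08,
                              respiration_amplitude_mm = 1.0) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            reading >= 1, reading <= nrow(cohort$readings))
  r <- cohort$readings[reading, ]
  width <- min(r$pulse_width_s, 0.9 / r$heart_rate_hz)
  list(chest = pulse_waveform_model(
         heart_rate_hz = r$heart_rate_hz,
         pulse_amplitude_mm = chest_amplitude_mm,
         pulse_width_s = width,
         respiration_amplitude_mm = respiration_amplitude_mm),
       wrist = pulse_waveform_model(
         heart_rate_hz = r$heart_rate_hz,
         pulse_amplitude_mm = wrist_amplitude_mm,
         pulse_width_s = width,
         ptt_delay_s = r$ptt_s))
}
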