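# Hemodynamic reference models linking vessel mechanics, pulse wave
# velocity, pulse transit time and blood pressure. These serve two roles:
# ground-truth link inside the synthetic-cohort generator, and reference
# forward/inverse relations for the regression layer.

#' Vessel mechanical properties
#'
#' Container for the arterial-wall parameters entering the Moens-Korteweg
#' and Hughes relations.
#'
#' @param E0 Zero-pressure elastic modulus of the vessel wall (Pa).
#' @param h0 Vessel wall thickness (m).
#' @param R0 Inner radius of the vessel (m).
#' @param rho Blood density (kg/m^3).
#' @param zeta Pressure coefficient of the exponential modulus-pressure
#'   relation (1/mmHg). Expressed per mmHg so that it composes with blood
#'   pressures in mmHg without unit conversion.
#' @return An object of class `vessel_properties`.
#' @export
#' @examples
#' vessel_properties(E0 = 1e5, h0 = 5e-4, R0 = 2e-3, rho = 1060, zeta = 0.017)
vessel_properties <- function(E0 = 1e5, h0 = 5e-4, R0 = 2e-3,
                              rho = 1060, zeta = 0.017) {
  stopifnot_positive(E0 = E0, h0 = h0, R0 = R0, rho = rho, zeta = zeta)
  structure(list(E0 = E0, h0 = h0, R0 = R0, rho = rho, zeta = zeta),
            class = "vessel_properties")
}

#' Blood-pressure model parameters
#'
#' Coefficients of the two scalar BP relations used throughout:
#' `BP = a * PWV^2 + b` and `BP = K1 / PTT + K2`.
#'
#' @param a Quadratic PWV coefficient (mmHg s^2 / m^2); must be positive.
#' @param b Offset of the PWV relation (mmHg).
#' @param K1 Inverse-PTT coefficient (mmHg s); must be positive so that BP
#'   decreases with PTT.
#' @param K2 Offset of the PTT relation (mmHg).
#' @return An object of class `bp_model_params`.
#' @export
bp_model_params <- function(a = 4, b = 60, K1 = 16.8, K2 = 0) {
  stopifnot_positive(a = a, K1 = K1)
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(K2), length(K2) == 1L, is.finite(K2))
  structure(list(a = a, b = b, K1 = K1, K2 = K2), class = "bp_model_params")
}

#' Subject profile
#'
#' Demographics and per-subject model constants used by the cohort
#' generator: arm length (heart-to-wrist path), the subject's PTT-BP
#' constants, and the baseline diastolic/systolic ranges the subject's
#' readings span.
#'
#' @param subject_id Identifier (integer or string).
#' @param age Age in years.
#' @param arm_length Heart-to-wrist arterial path length L (m); must lie
#'   in `[0.3, 1.0]`.
#' @param bp_params A [bp_model_params()] object.
#' @param baseline_dbp_range Length-2 numeric, low/high DBP (mmHg).
#' @param baseline_sbp_range Length-2 numeric, low/high SBP (mmHg).
#' @param pp_base Mid-range pulse pressure (mmHg).
#' @param note Free-text health note.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, age, arm_length, bp_params,
                            baseline_dbp_range, baseline_sbp_range,
                            pp_base = 45, note = "") {
  stopifnot(arm_length >= 0.3, arm_length <= 1.0,
            length(baseline_dbp_range) == 2L,
            length(baseline_sbp_range) == 2L,
            baseline_dbp_range[1] <= baseline_dbp_range[2],
            baseline_sbp_range[1] <= baseline_sbp_range[2],
            inherits(bp_params, "bp_model_params"))
  structure(list(subject_id = subject_id, age = age,
                 arm_length = arm_length, bp_params = bp_params,
                 baseline_dbp_range = baseline_dbp_range,
                 baseline_sbp_range = baseline_sbp_range,
                 pp_base = pp_base, note = note),
            class = "subject_profile")
}

#' Moens-Korteweg pulse wave velocity
#'
#' `PWV = sqrt(E * h0 / (2 * rho * R0))`: the propagation speed of the
#' arterial pressure pulse as a function of wall elastic modulus and
#' vessel geometry. Strictly increasing in `E`.
#'
#' @param E Elastic modulus of the vessel wall (Pa), positive.
#' @param vessel A [vessel_properties()] object.
#' @return Pulse wave velocity (m/s).
#' @export
#' @examples
#' moens_korteweg_pwv(4e5, vessel_properties(h0 = 5e-4, rho = 1060, R0 = 2e-3))
moens_korteweg_pwv <- function(E, vessel) {
  stopifnot(inherits(vessel, "vessel_properties"))
  stopifnot_positive(E = E)
  sqrt(E * vessel$h0 / (2 * vessel$rho * vessel$R0))
}

#' Hughes exponential modulus-pressure relation
#'
#' `E = E0 * exp(zeta * P)`: arterial elastic modulus stiffens
#' exponentially with transmural pressure.
#'
#' @param P Blood pressure (mmHg).
#' @param vessel A [vessel_properties()] object supplying `E0` and `zeta`.
#' @return Elastic modulus (Pa).
#' @export
hughes_modulus <- function(P, vessel) {
  stopifnot(inherits(vessel, "vessel_properties"), is.numeric(P))
  vessel$E0 * exp(vessel$zeta * P)
}

#' Blood pressure from pulse wave velocity
#'
#' Quadratic PWV-BP relation `BP = a * PWV^2 + b`.
#'
#' @param pwv Pulse wave velocity (m/s), non-negative.
#' @param params A [bp_model_params()] object.
#' @return Blood pressure (mmHg).
#' @export
bp_from_pwv <- function(pwv, params) {
  stopifnot(inherits(params, "bp_model_params"), all(pwv >= 0))
  params$a * pwv^2 + params$b
}

#' Blood pressure from pulse transit time (and its inverse)
#'
#' Hyperbolic PTT-BP relation `BP = K1 / PTT + K2`; BP is strictly
#' decreasing in PTT for `K1 > 0`. `ptt_from_bp()` inverts the relation,
#' `PTT = K1 / (BP - K2)`, and requires `bp > K2`.
#'
#' @param ptt Pulse transit time (s), strictly positive.
#' @param bp Blood pressure (mmHg), strictly greater than `K2`.
#' @param params A [bp_model_params()] object.
#' @return `bp_from_ptt()`: blood pressure (mmHg). `ptt_from_bp()`: pulse
#'   transit time (s).
#' @export
#' @examples
#' p <- bp_model_params(K1 = 20, K2 = 40)
#' bp_from_ptt(0.5, p)              # 80
#' ptt_from_bp(bp_from_ptt(0.21, p), p)  # 0.21
bp_from_ptt <- function(ptt, params) {
  stopifnot(inherits(params, "bp_model_params"))
  if (any(ptt <= 0)) stop("`ptt` must be strictly positive", call. = FALSE)
  params$K1 / ptt + params$K2
}

#' @rdname bp_from_ptt
#' @export
ptt_from_bp <- function(bp, params) {
  stopifnot(inherits(params, "bp_model_params"))
  if (any(bp <= params$K2)) {
    stop("`bp` must exceed K2 for the inverse PTT relation", call. = FALSE)
  }
  params$K1 / (bp - params$K2)
}

# Derive subject-specific K1/K2 from a common reference calibration that
# maps the cohort-wide DBP envelope onto the physiological PTT band
# [0.15, 0.30] s, with mild per-subject jitter (K1 scale, K2 offset).
# Keeping subjects near one shared line reproduces the pooled structure a
# multi-subject regression relies on while keeping the constants
# subject-dependent.
derive_bp_constants <- function(dbp_lo, dbp_hi, ptt_band = c(0.15, 0.30),
                                k1_jitter = 0, k2_jitter = 0) {
  stopifnot(dbp_hi > dbp_lo, ptt_band[1] < ptt_band[2])
  K1 <- (dbp_hi - dbp_lo) / (1 / ptt_band[1] - 1 / ptt_band[2])
  K2 <- dbp_lo - K1 / ptt_band[2]
  bp_model_params(K1 = K1 * (1 + k1_jitter), K2 = K2 + k2_jitter)
}
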