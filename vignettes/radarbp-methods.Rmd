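---
title: "Methods: radar-based cuffless blood-pressure estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radar-based cuffless blood-pressure estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radarbp)
```

## The measurement problem

Arterial blood pressure is usually read with an inflatable cuff:
accurate, but discrete, contact-based and uncomfortable. A
millimeter-wave FMCW radar pointed at bare skin can resolve
sub-millimeter skin motion in the *phase* of its de-chirped return — one
wavelength of two-way path change is $4\pi$ radians of phase, so at a
77 GHz carrier ($\lambda \approx 3.9$ mm) a 0.1 mm skin displacement is
about 0.3 rad, comfortably measurable. Two synchronized radars, one on
the chest and one on the wrist (at 79 GHz, to avoid interference), see
the same arterial pulse at two points along the arm. `radarbp`
implements the full chain from raw radar samples to blood-pressure
estimates, together with a synthetic generator that stands in for
human-subject recordings, which are not publicly available for this
kind of study.

Three physical relations anchor the method. The Moens–Korteweg equation
links the pulse wave velocity to vessel mechanics,

$$\mathrm{PWV} = \frac{L}{\mathrm{PTT}} = \sqrt{\frac{E\,h_0}{2\rho R_0}},$$

the Hughes relation makes the wall modulus pressure-dependent,
$E = E_0 e^{\zeta P}$, and two scalar regressions connect the
measurables to pressure: $BP = a\,\mathrm{PWV}^2 + b$ and the
hyperbolic form

$$BP = \frac{K_1}{\mathrm{PTT}} + K_2, \qquad K_1 > 0,$$

whose constants are subject-dependent. The hyperbolic form correlates
most strongly with diastolic pressure (DBP) and is the generative link
used by the cohort simulator (`bp_from_ptt()` / `ptt_from_bp()`).

## Signal chain

`process_cube()` runs the standard FMCW vital-sign chain:

1. **Range FFT** (`range_fft()`): per-frame FFT along fast time (Hann
   window by default; window and zero-padding configurable). Bin
   spacing follows from chirp slope and ADC rate: 0.098 m for the
   default 29.99 MHz/µs, 2.5 MHz, 128-sample configuration.
2. **Range-bin selection** (`select_range_bin()`): the subject is
   stationary, so one bin — the one with the largest *mean* magnitude
   across all frames — is used for the whole record. Per-frame argmax
   selection is deliberately avoided: it lets the bin hop under noise
   and corrupts the phase series. Ties go to the nearer bin with a
   warning; an optional dominance check (peak/median mean magnitude,
   used with threshold 3 by the pipeline front-end) rejects records
   with no detectable target.
3. **DC compensation** (`dc_compensate()`): the slow-time IQ series of
   the selected bin traces a circular arc; receiver DC shifts its
   centre and distorts the demodulated phase. The centre is estimated
   with the Kåsa linear least-squares circle fit and then refined with
   a deterministic Gauss–Newton pass on the geometric residuals
   $\lvert z - c\rvert - r$. The refinement matters: on noisy
   quarter-arcs the algebraic fit alone is biased by several percent of
   the radius, while the refined estimate is an order of magnitude
   closer (both behave identically on clean arcs, and the operation is
   idempotent). Collinear IQ points (no phase motion) are reported and
   left untouched.
4. **Arctangent demodulation and unwrapping**
   (`arctan_demodulate()`, `unwrap_phase()`): four-quadrant phase per
   frame, then $2\pi$ jump removal so successive differences are
   bounded by $\pi$.
5. **Displacement** (`phase_to_displacement()`):
   $d = \lambda\varphi/4\pi$, reported in mm, mean-removed by default.
   The sign convention (whether outward skin motion points up) is a
   configuration flag.

Chest traces can optionally be band-passed (`bandpass_trace()`, default
0.7–10 Hz) to suppress respiration before feature extraction. The
filter is a forward–backward cascade of second-order Butterworth
biquads with odd-reflection padding, i.e. zero-phase with ~36 dB
attenuation of a 0.25 Hz respiration line. An FFT brick-wall filter was
rejected: a respiration tone that is not periodic in the record leaks
across the whole pass band. Whether the original measurements were
filtered this way is not documented; the filter is therefore off by
default in `process_cube()` and its use is recorded in run manifests.

## Features

* **PTT** (`estimate_ptt()`): the lag maximizing the normalized
  cross-correlation of the chest and wrist traces over a physiological
  window (default 0.05–0.5 s), at the 0.5 ms frame resolution.
  Whole-trace correlation was chosen over per-beat fiducial timing: it
  needs no fiducial detection and averages over every beat in the
  record. Estimates whose peak correlation falls below 0.3 raise an
  error; a best lag pinned to a window edge is flagged, since a true
  delay below the window's lower bound is indistinguishable from it.
* **PWV** (`compute_pwv()`): $L/\mathrm{PTT}$ with $L$ the
  heart-to-wrist arm length.
* **AUC** (`compute_auc()`): peak-sharpness of the wrist pulse. Each of
  the three most *prominent* peaks (prominence, not raw height, so
  baseline drift cannot promote a drifted beat) is normalized to unit
  amplitude above its local valley baseline, and the area between the
  waveform and the half-amplitude line is integrated over the
  contiguous super-threshold region around the peak only, with the 0.5
  crossings located by linear interpolation. Restricting to the
  contiguous region keeps neighbouring beats out of the area; the local
  baseline makes the 50% line well-defined even on drifting traces. The
  record's AUC is the mean over the peaks, in seconds. For a
  raised-cosine peak of width $B$ the value is exactly $B/2\pi$, which
  the tests use as an analytic oracle (triangle $B/8$ and rectangle
  $W/2$ likewise).

## The synthetic cohort: what it states, and what it does not

Because the underlying human recordings are unavailable, the package
generates its own stated world (`generate_cohort()`), with five default
subjects whose ages, arm lengths and health notes mirror a small
mixed cohort (three healthy, one hypertensive, one older medicated
subject with much larger diastolic spread). Per reading:

* an activity condition (waking / rest / evening / post-exercise)
  places the true DBP within the subject's baseline range;
* pulse pressure is drawn around the subject's mid-range value, rising
  with DBP (about 0.5 mmHg per mmHg), so SBP = DBP + PP;
* the true PTT inverts the subject's hyperbolic PTT–BP relation;
* the systolic peak width is $w_c / \mathrm{PWV_{sys}}$ with
  $\mathrm{PWV_{sys}} = L/\mathrm{ptt\_from\_bp(SBP)}$ — the wall is
  stiffer at the instantaneous systolic pressure, so the upstroke
  travels faster and the peak sharpens as pressure rises.

The width choice deserves a note. Tying width to the *diastolic*
transit time would make the AUC feature a deterministic copy of PWV, so
a feature combination could never help and AUC could never be the
better systolic feature — contradicting both the intended behaviour of
the method and the zero-noise invariant (Spearman correlation of AUC
with SBP exactly −1) the generator is required to satisfy. Driving
width through the systolic-pressure wave speed preserves
"peaks sharpen as pressure rises" and gives the two features
complementary information, which is the mechanism the pooled
evaluation relies on.

Subject constants $K_1, K_2$ derive from one shared calibration mapping
the cohort DBP envelope onto PTT $\in [0.15, 0.3]$ s (consistent with
chest-to-wrist delays of roughly 200 ms), with small fixed per-subject
perturbations (±5% on $K_1$, ±2 mmHg on $K_2$). Mapping *each
subject's own range* onto the full PTT band instead would spread the
subjects' PTT–BP lines far apart and put a ~10 mmHg floor under any
pooled regression, which is incompatible with pooled errors in the
3–4 mmHg range; near-shared calibration with individual jitter is the
realistic middle ground.

Measurement noise (`noise_spec()`) is calibrated so each single
feature, fitted per subject, explains pressure to roughly 3–4 mmHg —
the level such radar readouts achieve in practice: PTT jitter 10 ms
(≈3.2 mmHg DBP-equivalent through $dBP/d\mathrm{PTT} = K_1/\mathrm{PTT}^2$),
width noise 6 ms (≈3.3 mmHg SBP-equivalent), pulse-pressure scatter
3 mmHg, cuff repeatability 1.5 mmHg. These values were fixed from that
calibration argument, not adjusted against test outcomes.

`cohort_features()` converts readings to feature records using the
closed form AUC $= \mathrm{width}/2\pi$; the equivalence of that closed
form with the full radar chain (cube → displacement → peak AUC) is
established separately by round-trip tests. This keeps 250-reading
evaluations fast while the radar-level path (`reading_to_models()`,
`synthesize_if_cube()`, `process_cube()`, `extract_features()`) remains
fully exercised at record scale.

What a green test does **not** establish: the generator has no motion
artifacts, no multipath or clothing attenuation, no dicrotic notch, no
beat-to-beat waveform variability beyond the modelled noise, and its
noise is Gaussian by construction. Passing the acceptance suite means
the *algorithms* behave as specified on the stated world, not that the
published human-subject error levels are reproduced.

## Regression layer

`fit_poly()` fits degree-3 polynomials (univariate powers, or for two
inputs every monomial $x_1^i x_2^j$ with $i+j \le 3$, matching the
univariate degree). Rank deficiency is reported with the names of the
deficient basis terms. Per-subject fit errors are training errors and
are labelled as such; `evaluate_models()` reports polynomial training
*and* test RMSE because the convention for the pooled polynomial is
ambiguous in this design.

`fit_mlp()` trains a small fully connected network (hidden sizes 20 and
10, tanh, linear output) by BFGS on the mean-squared error, under
5-fold cross-validation; the fold model with the lowest held-out
validation loss is kept, and features and response are standardized on
training folds only (verified by recomputation in the tests).
Two defaults are the package's own choices, exposed on `mlp_spec()`:

* `weight_decay = 1e-3` on standardized data — with ~175-row training
  sets and an essentially unregularized net, occasional optimizer runs
  land on sharp overfit minima and test error becomes erratic;
* `max_iters = 200` — a modest cap that doubles as early stopping
  (longer training measurably overfit in pilot runs, consistent with
  the observation that larger capacity overfits at this data volume).

`evaluate_models()` excludes the medicated outlier subject by default
(id 3), holds out a seeded random test split (25 of 200 usable
readings; proportional otherwise) and reports the 3 feature sets × 2
targets grid.

## Numerical and interface choices

* Tie-break in bin selection: nearest (lowest-index) bin, warned.
* Zero-magnitude IQ samples carry no phase; the previous phase is
  propagated with a warning.
* `unwrap_phase()` output differs from its input by exact multiples of
  $2\pi$; a jump of exactly $\pi$ is left alone.
* Cube files are little-endian interleaved I/Q int16, frames-major,
  with a JSON sidecar; the quantization step is a power of two
  (~15-bit dynamic range), so integer payloads round-trip
  bit-identically, and file size is validated against the sidecar
  configuration before reading.
* Every CLI stage writes a manifest (config hash, md5 checksums of
  inputs/outputs, all warnings); manifests contain no timestamps, so a
  seeded pipeline is byte-reproducible end to end.

## Known limitations

* PTT resolution equals the frame period (0.5 ms); no sub-sample
  interpolation of the correlation peak is attempted.
* The simulator synthesizes a single dominant scatterer per radar; bin
  selection on real multi-target scenes is untested.
* The AUC segment walk assumes peaks separated by genuine valleys;
  heavily merged beats (e.g. at very high heart rates with wide pulses)
  would blur the local baseline.
* The pooled regression inherits whatever subject-to-subject
  calibration spread the generator states; with real cohorts the
  per-subject constants are unknown and the pooled error floor may be
  substantially higher.
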