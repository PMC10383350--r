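# radarbp

Cuffless blood-pressure estimation from millimeter-wave FMCW radar, in R.

Two synchronized 77/79 GHz radars aimed at a person's chest and wrist see
the arterial pulse as sub-millimeter skin displacement, encoded in the
phase of the de-chirped radar return. From a pair of displacement traces
the package extracts:

* **PTT** — pulse transit time, the chest-to-wrist delay of the pulse
  wave (normalized cross-correlation, 0.5 ms resolution);
* **PWV** — pulse wave velocity, `PWV = L / PTT` with `L` the
  heart-to-wrist arm length;
* **AUC** — a pulse-sharpness feature: for each of the three most
  prominent wrist peaks, normalized to unit amplitude, the area between
  the waveform and the half-amplitude line (seconds); peaks sharpen as
  pressure rises, so AUC falls with blood pressure.

These feed degree-3 polynomial regressions and a small neural network
(hidden layers 20 and 10, BFGS, 5-fold cross-validation) that estimate
systolic and diastolic pressure (mmHg). The physical anchors are the
Moens–Korteweg equation `PWV = sqrt(E h0 / (2 rho R0))`, the Hughes
relation `E = E0 exp(zeta P)`, and the hyperbolic transit-time relation
`BP = K1/PTT + K2` (`K1 > 0`, subject-dependent).

Human radar/cuff recordings for this problem are not publicly
deposited, so the package carries a first-class synthetic generator:
ground-truth displacement traces, raw FMCW intermediate-frequency (IF)
cubes for a point target at 0.5 m, and whole five-subject cohorts (50
readings each under activity conditions that move blood pressure
around). Every downstream stage is tested against that stated world;
see `vignettes/radarbp-methods.Rmd` for what that does and does not
establish.

## Worked example

```r
library(radarbp)

cfg <- radar_config()     # 77 GHz, 0.5 ms frames, 10 s record
cfg
#> <radar_config> 77 GHz, slope 29.99 MHz/us, 128 samples @ 2.5 MHz
#>   20000 frames @ 0.5 ms (10.00 s record), wavelength 3.893 mm, bin 0.098 m

# ground-truth displacement: chest pulses 0.3 mm; wrist pulses 0.08 mm,
# delayed by a 210 ms transit time
chest <- generate_displacement(pulse_waveform_model(), cfg, radar_id = "chest")
wrist <- generate_displacement(
  pulse_waveform_model(pulse_amplitude_mm = 0.08, ptt_delay_s = 0.21),
  cfg, radar_id = "wrist")

# raw IF cube for the wrist radar at 0.5 m, with DC offset and 30 dB
# noise, then the full demodulation chain back to displacement
cube <- synthesize_if_cube(wrist, cfg, target_range_m = 0.5,
                           dc_offset = 0.4 - 0.3i, snr_db = 30, seed = 1)
rec <- process_cube(cube, radar_id = "wrist")

extract_features(chest, rec, arm_length = 0.725, subject_id = 1)
#>   subject_id ptt_s  pwv_mps      auc_s
#> 1          1  0.21 3.452381 0.03832738
```

The PTT comes back exactly (0.21 s), PWV = 0.725/0.21 = 3.45 m/s, and
the AUC is within 4% of the raised-cosine closed form
`0.25 / (2*pi) = 0.0398` s despite the injected noise.

Cohort-scale evaluation (250 synthetic readings, medicated outlier
subject excluded, 175/25 train/test split):

```r
coh <- generate_cohort(seed = 7)
report <- evaluate_models(cohort_features(coh), mlp_spec(seed = 7))
report
#> <evaluation_report> train 175 / test 25 (seed 7; excluded: 3)
#>  feature_set target poly_train_rmse poly_test_rmse ann_test_rmse
#>          pwv    sbp           5.533          6.450         6.450
#>          pwv    dbp           2.928          3.810         3.929
#>          auc    sbp           3.784          4.663         4.703
#>          auc    dbp           2.885          3.944         3.823
#>      pwv+auc    sbp           3.632          4.430         4.504
#>      pwv+auc    dbp           2.361          3.442         3.470
```

All RMSEs are in mmHg. The qualitative structure is the point: AUC is
the stronger single feature for systolic pressure, PWV/PTT for
diastolic, and the two combined beat either alone for both targets.

## Command line

```sh
Rscript inst/cli/radarbp.R pipeline --seed 7 --out run1
```

runs simulate → features → evaluate and writes `cohort.csv`,
`features.csv`, `report.json` plus per-stage `*.manifest.json` files
(config hash, md5 checksums, collected warnings; no timestamps, so a
seeded pipeline is byte-reproducible). The other subcommands —
`simulate`, `process` (raw IF cube → displacement CSV), `features`,
`fit`, `evaluate` — are described by `radarbp_cli(character(0))`.

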