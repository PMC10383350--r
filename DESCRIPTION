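Package: radarbp
Title: Cuffless Blood Pressure Estimation from Millimeter-Wave FMCW Radar
Version: 0.1.0
Authors@R: person("radarbp", "maintainers", email = "radarbp@example.org",
    role = c("aut", "cre"))
Description: Simulates and processes millimeter-wave frequency-modulated
    continuous-wave (FMCW) radar returns from chest and wrist skin
    displacement, extracts pulse transit time (PTT), pulse wave velocity
    (PWV) and an area-under-curve (AUC) pulse-sharpness feature, and
    estimates systolic and diastolic blood pressure with polynomial
    regression and a small feed-forward neural network. Includes a
    synthetic-cohort generator so the full pipeline is testable without
    human-subject recordings, a radar signal chain (range FFT, range-bin
    selection, least-squares DC compensation, arctangent demodulation,
    phase unwrapping), and a command-line interface tying the stages into
    one reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
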