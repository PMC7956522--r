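Package: ecgbp
Title: Multitask BiLSTM Blood Pressure Estimation from Single-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration-free continuous blood pressure estimation from
    single-lead electrocardiogram waveforms. Provides a synthetic paired
    ECG/ABP waveform generator with known ground truth, Daubechies-8
    discrete wavelet denoising with 125 to 100 Hz downsampling,
    skewness-based arterial blood pressure quality control and ground-truth
    extraction, a two-layer bidirectional LSTM trunk with three
    task-specific fully connected heads for systolic, diastolic and mean
    arterial pressure regression, joint training with an adaptive
    validation-trend task weighting scheme, and BHS/AAMI/Bland-Altman
    agreement evaluation, orchestrated as a reproducible end-to-end
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown,
    yaml
Config/testthat/edition: 3
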