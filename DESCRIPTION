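Package: fetalecg
Title: Non-Invasive Fetal Electrocardiography Processing Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for processing multichannel abdominal electrocardiograms to
    recover the fetal heart rate signal. Implements a multi-notch comb filter
    for powerline and baseline suppression, maternal ECG cancellation by
    continuously updated PQRST template subtraction with a first-derivative
    correction, fetal QRS detection with a bank of detection functions and
    RR-variability-based selection of the optimal one, autocorrelation signal
    quality scoring, amplitude-relationship (SNR) indices for abdominal
    signals, clinical fetal-heart-rate variability reports (basal rate,
    accelerations, decelerations, STV/LTV and related indices), beat-annotation
    scoring against a reference (Se, PPV, F1, RR accuracy) and a calibrated
    synthetic record generator with ground-truth annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
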