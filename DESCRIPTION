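Package: hrvmspc
Title: Heart Rate Variability Monitoring and Seizure Warning with
    Multivariate Statistical Process Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Real-time heart rate variability (HRV) monitoring from
    beat-to-beat R-R intervals (RRI): streaming artifact rejection and
    missed-beat compensation with median-absolute-deviation limits,
    sliding-window extraction of eight time- and frequency-domain HRV
    indices (cubic-spline tachogram resampling and autoregressive Burg
    spectra), anomaly detection by principal-component multivariate
    statistical process control using the Q (squared prediction error)
    and Hotelling T2 statistics with empirical control limits, a
    persistence-debounced two-state alarm machine for preictal warning,
    evaluation metrics used in seizure-prediction studies (sensitivity
    within a prediction horizon, false positives per hour, exact
    one-sided sign tests, Bland-Altman agreement, measurement failure
    summaries), and a deterministic synthetic RRI generator for
    end-to-end validation without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    MASS,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
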