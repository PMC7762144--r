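Package: specratio
Title: Frequency-Band Spectral Power Ratios for Multivariate Stationary Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the distribution of spectral power across
    frequency bands in multivariate stationary processes whose dimensions may
    differ. Estimates kernel-smoothed spectral matrices from multi-epoch
    recordings, computes the dimension-blind frequency-specific spectral ratio
    (FS-ratio) of band power to total power, discovers power-carrying bands
    with a scan statistic, tests equality of same-dimension spectral matrices
    via an L2 statistic with a normal approximation, and quantifies FS-ratio
    uncertainty with the stationary block bootstrap, including automatic
    block-length selection. Ships a simulator for autoregressive and
    vector-autoregressive epoch designs used to validate the methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
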