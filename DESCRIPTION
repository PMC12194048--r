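Package: vbpbb
Title: Variable Bandpass Periodic Block Bootstrap for Periodically
    Correlated Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Isolates periodically correlated (PC) components of a
    regularly sampled time series with Kolmogorov-Zurbenko Fourier
    Transform (KZFT) bandpass filters, bootstraps each component with
    period-aligned blocks (the variable bandpass periodic block
    bootstrap, VBPBB), and builds percentile confidence-interval bands
    for the periodic means.  A generalized seasonal block bootstrap
    (GSBB) baseline on the unfiltered series, band-width comparisons, a
    significance rule for periodic mean variation, component summation,
    an FFT periodogram for frequency screening, and a synthetic-data
    generator with known periodic structure are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
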