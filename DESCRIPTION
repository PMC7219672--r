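Package: fractalfall
Title: Fractal-Feature Fall Detection from Wearable Accelerometer Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects falls in triaxial accelerometer recordings from a
    pelvis-worn sensor by exploiting the fractal dynamics of the acceleration
    sum-vector. Provides windowed preprocessing, a multi-level Daubechies-4
    discrete wavelet transform with periodic boundary handling (both a
    convolve-then-downsample reference and a fused strided form), per-level
    wavelet-variance estimates of the spectral exponent, Hurst exponent and
    fractal dimension, an offline ARFIMA-based fractal analysis with
    fractional differencing and grid model selection, ADF/KPSS stationarity
    testing with field-standard lag rules, and a two-class linear discriminant
    fall/no-fall classifier. Seeded generators for fractional Gaussian noise,
    ARFIMA series and synthetic fall/activity windows support fully
    reproducible experiments without sensor hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
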