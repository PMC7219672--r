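# fractalfall

Falls are the leading cause of injury death in older adults, and wearable
fall-detection systems reduce the harm of a fall mainly by shortening the
time to medical aid. `fractalfall` implements a fall-detection pipeline for
pelvis-worn triaxial accelerometers (32 Hz, ±8 g) that classifies falls
against activities of daily life (ADL) using *fractal* features: per-window
estimates of the signal's spectral exponent, Hurst exponent and fractal
dimension, computed in real time from a multi-level wavelet transform.

It is aimed at researchers in biomedical signal processing who want a
tested, reproducible software reference for this class of algorithm —
including seeded synthetic-signal generators that stand in for the sensor
front-end, so every experiment in the package runs without hardware or an
external dataset.

## The method

For each 128-sample window (50% overlap) of the acceleration sum-vector
`a' = sqrt(ax² + ay² + az²)`:

1. zero-mean the window, `a = a' − μ_a'`, and record `μ_a'` and the
   unbiased variance `σ²_a'`;
2. apply a 4-level Daubechies-4 (8-tap) DWT with periodic boundary
   handling, giving approximations `A1..A4` and details `D1..D4`. The
   transform is implemented twice — a convolve-then-downsample reference
   and a fused form that computes only the retained coefficients by
   striding across the periodically extended signal — and the two are
   required to agree to 1e-12;
3. for each level `i`, estimate the spectral exponent from the
   detail-variance ratio, `β_s = log2(var(D_i)/σ²_a)/i`, convert to the
   exponent of the underlying non-stationary process (`β = β_s + 2`, one
   integration order up), and chain `H = (β − 1)/2`, `fd = 2 − H`;
4. classify the 14-dimensional feature vector
   `[A4 (8), μ_a', σ²_a', fd1..fd4]` with a two-class pooled-covariance
   linear discriminant; scores `w'x + b ≥ 0` are calls of "fall".

Offline, the same fractal parameters are obtained rigorously by ARFIMA
analysis: the window is first-differenced to a stationary series (verified
by an ADF/KPSS double-validation battery), an ARFIMA(r, d, q) grid is
fitted by profile likelihood with AIC selection, and the stationary order
`d` is converted back to the original process via
`d̃ = d + 1, β = 2d̃, H = (β − 1)/2, fd = 2 − H` (equivalently
`fd = 1.5 − d`).

## Worked example

```r
library(fractalfall)
library(dplyr)

# a seeded synthetic dataset: 100 fall + 100 ADL windows
d     <- gen_labelled_dataset(100, 100, sim_config(seed = 5))
feats <- extract_features(d)

feats |>
  group_by(label) |>
  summarise(across(c(var, fd1, fd4), mean))
#> # A tibble: 2 × 4
#>   label   var   fd1   fd4
#>   <chr> <dbl> <dbl> <dbl>
#> 1 adl   0.105  3.78  1.32
#> 2 fall  0.258  2.26  1.35

cv <- crossval_lda(feats, seed = 1)
mean(cv$accuracy)
#> [1] 0.97
```

Fall windows carry a much larger window variance (the impact transient)
and a systematically *lower* level-1 fractal dimension than ADL windows —
the irregularity contrast the classifier exploits — and stratified 5-fold
LDA separates the two classes at ~97% accuracy on the default synthetic
conditions.

The per-activity conversion chain, applied to the bundled reference table
of fractional-integration orders:

```r
ref <- activity_fractal_reference()
nonstationary_fractal_params(d_tilde = ref$d_tilde) |>
  mutate(activity = ref$activity, .before = 1)
#> # A tibble: 6 × 6
#>   activity                d d_tilde  beta  hurst    fd
#>   <chr>               <dbl>   <dbl> <dbl>  <dbl> <dbl>
#> 1 falls               0.49    1.49   2.98 0.99    1.01
#> 2 walking            -0.482   0.518  1.04 0.0180  1.98
#> 3 kneeling_down      -0.446   0.554  1.11 0.0540  1.95
#> 4 sitting_down       -0.001   0.999  2.00 0.499   1.50
#> 5 standing_up        -0.01    0.990  1.98 0.490   1.51
#> 6 picking_up_objects -0.301   0.699  1.40 0.199   1.80
```

Falls sit near `fd = 1.01` while every daily activity is at 1.5 or above,
which is why the fractal dimension is a strong fall discriminant.

## Command line

A thin Rscript front-end (`inst/exec/fractalfall`) exposes the pipeline as
subcommands:

```sh
fractalfall simulate --falls 500 --adls 500 --seed 7 --out data.csv
fractalfall extract-features --input data.csv --out features.csv
fractalfall train --features features.csv --model model.json
fractalfall evaluate --features features.csv --model model.json --out metrics.json
fractalfall stationarity --input data.csv --out verdicts.csv
fractalfall fractal-analysis --input data.csv --out arfima.csv --grid 4,4
```

CSV schemas: accelerometer files have a header with at least `ax, ay, az`
(units g; optional `time`, `window_id`, `label`); feature files carry
`window_id, start_index[, label]`, the 14 feature columns
`a4_1..a4_8, mu, var, fd1..fd4`, plus `sd` and `fd_undefined`. Models are
versioned JSON documents.

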