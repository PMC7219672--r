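#' Simulation configuration for synthetic sensor windows
#'
#' Bundles the parameters of the synthetic accelerometer front-end. The
#' defaults emulate a pelvis-worn 32 Hz, +/-8 g sensor: fall windows are a
#' quiet ~1 g gravity baseline broken by one short high-amplitude impact
#' spike; activity (ADL) windows carry a few episodic low-frequency
#' oscillation bursts. Amplitude and rate ranges are per-window uniform
#' draws.
#'
#' @param seed Integer seed; fully determines generated windows.
#' @param n Window length in samples (default 128).
#' @param fs Sampling rate in Hz (default 32).
#' @param quantize_bits Optional ADC resolution; `12L` emulates the sensor,
#'   `NULL` (default) leaves values continuous.
#' @param baseline_g Gravity baseline magnitude in g.
#' @param spike_amplitude_g Range of the impact-spike peak amplitude in g.
#' @param spike_width_samples Range (integer) of the spike width in samples.
#' @param noise_sd_g Per-axis Gaussian noise standard deviation in g.
#' @param adl_episodes Integer range of oscillation episodes per ADL window.
#' @param adl_amplitude_g Range of per-episode oscillation amplitude in g.
#' @param adl_freq_hz Range of per-episode oscillation frequency in Hz.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n = 128L, fs = 32, quantize_bits = NULL,
                       baseline_g = 1.0, spike_amplitude_g = c(3, 7),
                       spike_width_samples = c(3L, 8L), noise_sd_g = 0.05,
                       adl_episodes = c(2L, 5L), adl_amplitude_g = c(0.3, 1.5),
                       adl_freq_hz = c(0.5, 3)) {
  structure(
    list(
      seed = as.integer(seed), n = as.integer(n), fs = fs,
      quantize_bits = quantize_bits, baseline_g = baseline_g,
      spike_amplitude_g = spike_amplitude_g,
      spike_width_samples = as.integer(spike_width_samples),
      noise_sd_g = noise_sd_g, adl_episodes = as.integer(adl_episodes),
      adl_amplitude_g = adl_amplitude_g, adl_freq_hz = adl_freq_hz
    ),
    class = "sim_config"
  )
}

# closed-form fGn autocovariance
fgn_autocovariance <- function(k, h) {
  0.5 * (abs(k + 1)^(2 * h) - 2 * abs(k)^(2 * h) + abs(k - 1)^(2 * h))
}

#' Fractional Gaussian noise with a known Hurst exponent
#'
#' Draws an exact stationary fGn sample by circulant embedding of the
#' autocovariance `rho(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}) / 2`
#' (the Davies-Harte construction). If the circulant eigenvalues are not
#' non-negative at this length (possible for extreme `H`), the draw falls
#' back to the sequential conditional (Hosking) recursion, which is exact
#' but O(n^2).
#'
#' @param h Hurst exponent in (0, 1). `h = 0.5` is white noise.
#' @param n Number of samples.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of length `n` with unit marginal variance.
#' @examples
#' x <- gen_fgn(0.7, 256, seed = 1)
#' @export
gen_fgn <- function(h, n, seed = NULL) {
  if (!is.numeric(h) || h <= 0 || h >= 1) abort("`h` must be in (0, 1).")
  n <- as.integer(n)
  if (n < 1L) abort("`n` must be >= 1.")
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- 2L * n
  r <- fgn_autocovariance(0:(m %/% 2L), h)
  circ <- c(r, rev(r[2:(m %/% 2L)]))
  lam <- Re(fft(circ))
  if (min(lam) < -1e-8 * max(lam)) {
    return(.fgn_hosking(h, n))
  }
  lam[lam < 0] <- 0
  z <- complex(real = rnorm(m), imaginary = rnorm(m))
  # real part only, so scale by lam/m (not lam/2m) for unit marginal variance
  x <- Re(fft(sqrt(lam / (2 * m)) * z)) * sqrt(2)
  x[seq_len(n)]
}

# exact sequential conditional sampler (Levinson-Durbin recursion)
.fgn_hosking <- function(h, n) {
  gamma <- fgn_autocovariance(0:(n - 1L), h)
  x <- numeric(n)
  phi <- numeric(0)
  v <- gamma[1]
  x[1] <- rnorm(1) * sqrt(v)
  for (t in seq_len(n - 1L)) {
    if (t == 1L) {
      phi <- gamma[2] / gamma[1]
    } else {
      kappa <- (gamma[t + 1] - sum(phi * gamma[t:2])) / v
      phi <- c(phi - kappa * rev(phi), kappa)
    }
    v <- gamma[1] - sum(phi * gamma[(t + 1):2])
    mu <- sum(phi * x[t:1])
    x[t + 1] <- mu + rnorm(1) * sqrt(max(v, 0))
  }
  x
}

#' Simulate an ARFIMA(r, d, q) series
#'
#' Gaussian innovations are passed through the MA polynomial, fractionally
#' integrated by the binomial weights of `(1 - L)^{-d}`, then fed through
#' the AR recursion; a burn-in of `max(500, n/4)` samples is discarded so
#' the output is effectively stationary.
#'
#' @param n Output length.
#' @param d Fractional order, `|d| < 0.5`.
#' @param ar,ma Numeric AR and MA coefficient vectors (may be empty). The AR
#'   polynomial must be stationary and the MA polynomial invertible (roots
#'   outside the unit circle).
#' @param seed Optional integer seed.
#' @param innov_sd Innovation standard deviation (default 1).
#' @return Numeric vector of length `n`.
#' @examples
#' s <- gen_arfima_series(1024, d = 0.3, ar = 0.5, ma = 0.3, seed = 7)
#' @export
gen_arfima_series <- function(n, d, ar = numeric(), ma = numeric(),
                              seed = NULL, innov_sd = 1) {
  n <- as.integer(n)
  if (abs(d) >= 0.5) abort("`d` must satisfy |d| < 0.5.")
  if (length(ar) && any(Mod(polyroot(c(1, -ar))) <= 1 + 1e-8)) {
    abort("AR polynomial is not stationary (root inside the unit circle).")
  }
  if (length(ma) && any(Mod(polyroot(c(1, ma))) <= 1 + 1e-8)) {
    abort("MA polynomial is not invertible (root inside the unit circle).")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  burn <- max(500L, n %/% 4L)
  m <- n + burn
  e <- rnorm(m, sd = innov_sd)
  u <- if (length(ma)) {
    v <- as.vector(stats::filter(e, c(1, ma), method = "convolution",
                                 sides = 1))
    v[seq_along(ma)] <- e[seq_along(ma)]
    v
  } else {
    e
  }
  z <- fractional_difference(u, -d)
  s <- if (length(ar)) {
    as.vector(stats::filter(z, ar, method = "recursive"))
  } else {
    z
  }
  s[(burn + 1L):m]
}

# distribute a magnitude time course onto three axes along a fixed random
# unit direction, on top of a gravity baseline on az; the vertical component
# is kept non-negative so movement magnitude adds to (never cancels) gravity
.axes_from_magnitude <- function(pulse, cfg) {
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  u[3] <- abs(u[3])
  noise <- matrix(rnorm(3 * cfg$n, sd = cfg$noise_sd_g), ncol = 3)
  out <- tibble::tibble(
    t = (seq_len(cfg$n) - 1L) / cfg$fs,
    ax = u[1] * pulse + noise[, 1],
    ay = u[2] * pulse + noise[, 2],
    az = cfg$baseline_g + u[3] * pulse + noise[, 3]
  )
  if (!is.null(cfg$quantize_bits)) {
    for (col in c("ax", "ay", "az")) {
      out[[col]] <- quantize_signal(out[[col]], cfg$quantize_bits)
    }
  }
  clip <- function(v) pmin(pmax(v, -8), 8)
  if (any(abs(c(out$ax, out$ay, out$az)) > 8)) {
    warn("synthetic window clipped to the +/-8 g sensor range.")
    out$ax <- clip(out$ax); out$ay <- clip(out$ay); out$az <- clip(out$az)
  }
  out
}

#' Synthetic fall window
#'
#' One 128-sample triaxial window: a ~1 g gravity baseline with per-axis
#' Gaussian noise, broken by a single impact transient of random amplitude,
#' width and position. The transient has the sharp-rise/fast-decay shape of
#' a body impact (a one-sample jump to the peak followed by an exponential
#' decay), which makes it broadband -- the signature the wavelet features
#' key on. Uses (and advances) the session RNG; seed via `set.seed()` or
#' [gen_labelled_dataset()].
#'
#' @param cfg A [sim_config()].
#' @return A tibble `t`, `ax`, `ay`, `az` with attribute `label = "fall"`.
#' @export
gen_fall_window <- function(cfg = sim_config()) {
  pulse <- numeric(cfg$n)
  amp <- runif(1, cfg$spike_amplitude_g[1], cfg$spike_amplitude_g[2])
  w <- sample(cfg$spike_width_samples[1]:cfg$spike_width_samples[2], 1)
  centre <- sample(seq(16L, cfg$n - 16L), 1)
  pulse[centre + seq_len(w) - 1L] <- amp * exp(-(seq_len(w) - 1) / (w / 3))
  out <- .axes_from_magnitude(pulse, cfg)
  attr(out, "label") <- "fall"
  out
}

#' Synthetic activity (ADL) window
#'
#' One 128-sample triaxial window of episodic band-limited oscillation: a
#' random number of Hann-windowed sinusoid bursts of modest amplitude and
#' 0.5-3 Hz frequency on the gravity baseline, emulating walking-like
#' movement rather than an impact.
#'
#' @param cfg A [sim_config()].
#' @param episodes Optional fixed episode count (default: drawn from
#'   `cfg$adl_episodes`); `0` gives a noise-only window.
#' @return A tibble `t`, `ax`, `ay`, `az` with attribute `label = "adl"`.
#' @export
gen_adl_window <- function(cfg = sim_config(), episodes = NULL) {
  k <- if (is.null(episodes)) {
    sample(cfg$adl_episodes[1]:cfg$adl_episodes[2], 1)
  } else {
    as.integer(episodes)
  }
  pulse <- numeric(cfg$n)
  for (i in seq_len(k)) {
    amp <- runif(1, cfg$adl_amplitude_g[1], cfg$adl_amplitude_g[2])
    freq <- runif(1, cfg$adl_freq_hz[1], cfg$adl_freq_hz[2])
    dur <- sample(seq(32L, 96L), 1)
    start <- sample(seq_len(cfg$n - dur), 1)
    tt <- seq_len(dur)
    env <- 0.5 * (1 - cos(2 * pi * tt / (dur + 1)))
    pulse[start + tt - 1L] <- pulse[start + tt - 1L] +
      amp * env * sin(2 * pi * freq * tt / cfg$fs + runif(1, 0, 2 * pi))
  }
  out <- .axes_from_magnitude(pulse, cfg)
  attr(out, "label") <- "adl"
  out
}

#' Seeded labelled dataset of synthetic fall and ADL windows
#'
#' Generates `n_fall` fall and `n_adl` activity windows under one
#' configuration, shuffles their order, and stacks them into one long
#' tibble compatible with [extract_features()] and the CSV reader/writer.
#'
#' @param n_fall,n_adl Non-negative window counts per class.
#' @param cfg A [sim_config()]; its `seed` drives all randomness, so equal
#'   configurations reproduce bit-identical datasets.
#' @return A tibble with columns `window_id`, `label` (`"fall"`/`"adl"`),
#'   `t`, `ax`, `ay`, `az`; `128 * (n_fall + n_adl)` rows.
#' @examples
#' d <- gen_labelled_dataset(5, 5, sim_config(seed = 42))
#' dplyr::count(d, label)
#' @export
gen_labelled_dataset <- function(n_fall, n_adl, cfg = sim_config()) {
  if (n_fall < 0 || n_adl < 0) abort("window counts must be >= 0.")
  set.seed(cfg$seed)
  labels <- sample(rep(c("fall", "adl"), c(n_fall, n_adl)))
  purrr::imap_dfr(labels, function(lab, i) {
    w <- if (lab == "fall") gen_fall_window(cfg) else gen_adl_window(cfg)
    dplyr::mutate(w, window_id = as.integer(i), label = lab, .before = 1)
  })
}
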