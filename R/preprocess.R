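#' Acceleration sum-vector magnitude
#'
#' Collapses the three acceleration axes into a single orientation-free
#' magnitude signal, `sqrt(ax^2 + ay^2 + az^2)`, the standard first step of
#' accelerometer activity pipelines. A subject at rest reads about 1 g.
#'
#' @param accel A data frame with numeric columns `ax`, `ay`, `az` (units g).
#'   Any other columns (e.g. `time`, `window_id`, `label`) are kept.
#' @param range_g Soft full-scale check: values with magnitude above this
#'   trigger a warning (the emulated sensor saturates at +/- 8 g) but are not
#'   altered.
#'
#' @return The input as a tibble with an added numeric column `a_sum`.
#' @examples
#' sum_vector(tibble::tibble(ax = c(0, 3), ay = c(0, 4), az = c(0, 0)))
#' @export
sum_vector <- function(accel, range_g = 8) {
  accel <- as_accel(accel)
  over <- abs(c(accel$ax, accel$ay, accel$az)) > range_g
  if (any(over)) {
    warn(sprintf(
      "%d acceleration values exceed the +/-%g g sensor range.",
      sum(over), range_g
    ))
  }
  dplyr::mutate(accel, a_sum = sqrt(.data$ax^2 + .data$ay^2 + .data$az^2))
}

# validate a triaxial segment data frame
as_accel <- function(accel) {
  if (!is.data.frame(accel)) abort("`accel` must be a data frame.")
  missing_cols <- setdiff(c("ax", "ay", "az"), names(accel))
  if (length(missing_cols)) {
    abort(paste0("`accel` is missing columns: ", toString(missing_cols)))
  }
  for (col in c("ax", "ay", "az")) check_numeric(accel[[col]], col)
  tibble::as_tibble(accel)
}

#' Segment a signal into fixed-length overlapping windows
#'
#' Splits a stream into windows of `n` samples whose starts advance by
#' `hop = n * (1 - overlap)` samples. Trailing samples that do not fill a
#' complete window are discarded: the downstream transform operates on fixed
#' 128-sample blocks only.
#'
#' @param x Numeric vector, the signal to segment.
#' @param n Window length in samples (even, >= 16). Default 128.
#' @param overlap Fraction of overlap between consecutive windows, in
#'   `[0, 1)`. Default 0.5 (50% overlap, hop of `n/2`).
#'
#' @return A tibble with one row per window: `start_index` (0-based sample
#'   offset of the window in `x`) and `samples`, a list-column of numeric
#'   vectors of length `n`. Zero rows (with a warning) if `x` is shorter
#'   than `n`.
#' @examples
#' segment_windows(sin(1:256 / 10), n = 128)  # starts 0, 64, 128
#' @export
segment_windows <- function(x, n = 128L, overlap = 0.5) {
  check_numeric(x, "x")
  n <- as.integer(n)
  if (n < 16L || n %% 2L != 0L) abort("`n` must be an even integer >= 16.")
  if (!is.numeric(overlap) || overlap < 0 || overlap >= 1) {
    abort("`overlap` must be in [0, 1).")
  }
  if (length(x) < n) {
    warn(sprintf("stream of %d samples is shorter than one %d-sample window.",
                 length(x), n))
    return(tibble::tibble(start_index = integer(), samples = list()))
  }
  hop <- max(1L, as.integer(floor(n * (1 - overlap))))
  starts <- seq(0L, length(x) - n, by = hop)
  tibble::tibble(
    start_index = starts,
    samples = lapply(starts, function(s) x[(s + 1L):(s + n)])
  )
}

#' Zero-mean window with its summary statistics
#'
#' Wraps one sum-vector window into the form the feature extractor consumes:
#' the raw window `a_prime`, its mean `mu_a_prime` and unbiased variance
#' `var_a_prime` (divisor N-1), the zero-mean signal `a = a_prime -
#' mu_a_prime`, and `var_a`. By translation invariance `var_a` equals
#' `var_a_prime`; both are kept because the mean/variance of the raw window
#' are classifier features while the zero-mean variance anchors the fractal
#' estimator.
#'
#' @param window Numeric vector of sum-vector samples (length >= 2).
#' @param start_index 0-based offset of the window in its source stream.
#' @return An object of class `windowed_signal`.
#' @examples
#' ws <- windowed_signal(c(1, 2, 3, 4))
#' ws$mu_a_prime   # 2.5
#' ws$var_a_prime  # 5/3
#' @export
windowed_signal <- function(window, start_index = 0L) {
  check_numeric(window, "window", min_len = 2L)
  mu <- mean(window)
  a <- window - mu
  structure(
    list(
      a_prime = window,
      mu_a_prime = mu,
      var_a_prime = var(window),
      a = a,
      var_a = var(a),
      n = length(window),
      start_index = as.integer(start_index)
    ),
    class = "windowed_signal"
  )
}

#' @export
print.windowed_signal <- function(x, ...) {
  cat(sprintf(
    "<windowed_signal> n = %d, start = %d, mean = %.4g, var = %.4g\n",
    x$n, x$start_index, x$mu_a_prime, x$var_a_prime
  ))
  invisible(x)
}

#' Quantize a signal to an ADC grid
#'
#' Emulates the sensor's analog-to-digital converter: values are snapped to a
#' uniform grid of `2^bits` codes spanning `[-range_g, range_g]`. Used only
#' when simulating the sensor front-end; real recordings are never
#' re-quantized by the pipeline.
#'
#' @param x Numeric vector in g.
#' @param bits ADC resolution in bits (default 12, the reference sensor).
#' @param range_g Full-scale range in g (default 8).
#' @return Numeric vector on the quantization grid, clipped to full scale.
#' @export
quantize_signal <- function(x, bits = 12L, range_g = 8) {
  check_numeric(x, "x")
  step <- (2 * range_g) / (2^bits)
  pmin(pmax(round(x / step) * step, -range_g), range_g - step)
}
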