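#' Daubechies-4 analysis filter pair
#'
#' Returns the 8-tap orthonormal Daubechies filter pair (4 vanishing moments)
#' used throughout the transform. The lowpass filter `h` is the standard
#' decomposition orientation (time-reversed scaling coefficients); the
#' highpass `g` is its quadrature mirror, `g[k] = (-1)^k h[7 - k]` (0-based).
#' Invariants: `sum(h) = sqrt(2)`, `sum(g) = 0`, both have unit energy, and
#' the even shifts of `h` are mutually orthogonal.
#'
#' @return An object of class `wavelet_filters`: a list with numeric `h`,
#'   `g` (length 8) and `name`.
#' @examples
#' f <- db4_filters()
#' sum(f$h)  # sqrt(2)
#' @export
db4_filters <- function() {
  # orthonormal scaling coefficients, 4 vanishing moments
  scaling <- c(
    0.23037781330885523, 0.71484657055254150, 0.63088076792959040,
    -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
    0.03288301166698295, -0.01059740178499728
  )
  h <- rev(scaling)                     # decomposition (analysis) orientation
  g <- (-1)^(0:7) * rev(h)              # quadrature mirror
  structure(list(h = h, g = g, name = "db4-8tap"), class = "wavelet_filters")
}

#' @export
print.wavelet_filters <- function(x, ...) {
  cat(sprintf("<wavelet_filters> %s (%d taps)\n", x$name, length(x$h)))
  invisible(x)
}

#' Periodic (circular) extension of a signal
#'
#' Prepends the last `taps - 2` samples of `x` so that every filter placement
#' whose output the strided transform retains reads only values of the
#' wrapped signal. This is the padding step the fused transform applies
#' before each level.
#'
#' @param x Numeric vector of even length `N >= taps`.
#' @param taps Filter length (default 8).
#' @return Numeric vector of length `N + taps - 2`.
#' @export
periodic_extend <- function(x, taps = 8L) {
  check_numeric(x, "x")
  n <- length(x)
  taps <- as.integer(taps)
  if (n < taps) abort("`x` must be at least as long as the filter.")
  if (n %% 2L != 0L) abort("`x` must have even length.")
  c(x[(n - taps + 3L):n], x)
}

#' One DWT level, convolve-then-downsample reference form
#'
#' The ground-truth single-level transform: circular convolution of `x` with
#' each filter over the full period, then retention of the odd-indexed
#' outputs (`y[2k + 1]`, 0-based). The downsampling phase is a frozen
#' convention; the fused form below must reproduce it exactly.
#'
#' @param x Numeric vector of even length >= 8.
#' @param filters A [db4_filters()]-style filter pair.
#' @return A list with numeric `A` (approximations) and `D` (details), each
#'   of length `length(x)/2`.
#' @export
dwt_level_reference <- function(x, filters = db4_filters()) {
  check_numeric(x, "x")
  n <- length(x)
  if (n %% 2L != 0L) abort("`x` must have even length.")
  if (n < 8L) abort("`x` must have at least 8 samples.")
  circ <- function(f) {
    taps <- length(f)
    y <- vapply(0:(n - 1L), function(nn) {
      sum(f * x[((nn - 0:(taps - 1L)) %% n) + 1L])
    }, numeric(1))
    y[seq(2L, n, by = 2L)]              # odd phase, 0-based y[2k + 1]
  }
  list(A = circ(filters$h), D = circ(filters$g))
}

#' One DWT level, fused strided form
#'
#' Computes only the retained coefficients by striding two samples at a time
#' across the periodically extended signal with the filters stored in
#' reversed order, fusing the downsampling into the convolution. Must agree
#' with [dwt_level_reference()] to within 1e-12; that equivalence is the
#' module's central invariant.
#'
#' @inheritParams dwt_level_reference
#' @return A list with numeric `A` and `D`, each of length `length(x)/2`.
#' @export
dwt_level_fused <- function(x, filters = db4_filters()) {
  check_numeric(x, "x")
  n <- length(x)
  if (n %% 2L != 0L) abort("`x` must have even length.")
  if (n < 8L) abort("`x` must have at least 8 samples.")
  taps <- length(filters$h)
  xe <- periodic_extend(x, taps)
  hr <- rev(filters$h)
  gr <- rev(filters$g)
  half <- n %/% 2L
  # slice matrix: row k holds xe[2k .. 2k + taps - 1] (0-based), i.e. the
  # samples under filter placement 2k + 1 of the circular convolution
  idx <- outer(seq(0L, n - 2L, by = 2L), seq_len(taps), `+`)
  xm <- matrix(xe[idx], nrow = half)
  list(A = as.vector(xm %*% hr), D = as.vector(xm %*% gr))
}

#' Multi-level discrete wavelet transform
#'
#' Repeats the single-level transform `levels` times, each level consuming
#' the previous approximations, to give the coefficient pyramid
#' `A1..AL, D1..DL`. With the default 128-sample window and 4 levels, the
#' final approximations and details are each 8 coefficients long.
#'
#' @param x Numeric vector whose length is divisible by `2^levels`.
#' @param levels Number of decomposition levels (default 4).
#' @param filters Filter pair, see [db4_filters()].
#' @param method `"fused"` (default) or `"reference"`.
#' @return An object of class `wavelet_decomposition`: list with `A` and `D`
#'   (lists of numeric vectors, finest level first), `levels`,
#'   `input_length`.
#' @examples
#' dec <- multilevel_dwt(rnorm(128))
#' lengths(dec$D)  # 64 32 16 8
#' @export
multilevel_dwt <- function(x, levels = 4L, filters = db4_filters(),
                           method = c("fused", "reference")) {
  method <- match.arg(method)
  check_numeric(x, "x")
  levels <- as.integer(levels)
  if (levels < 1L) abort("`levels` must be >= 1.")
  if (length(x) %% (2L^levels) != 0L) {
    abort(sprintf("length(x) = %d is not divisible by 2^%d.",
                  length(x), levels))
  }
  if (length(x) %/% (2L^(levels - 1L)) < 8L) {
    abort("signal too short for the requested number of levels.")
  }
  step <- if (method == "fused") dwt_level_fused else dwt_level_reference
  A <- vector("list", levels)
  D <- vector("list", levels)
  cur <- x
  for (i in seq_len(levels)) {
    lev <- step(cur, filters)
    A[[i]] <- lev$A
    D[[i]] <- lev$D
    cur <- lev$A
  }
  structure(
    list(A = A, D = D, levels = levels, input_length = length(x)),
    class = "wavelet_decomposition"
  )
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf(
    "<wavelet_decomposition> %d levels of a %d-sample signal (A%d/D%d length %d)\n",
    x$levels, x$input_length, x$levels, x$levels, length(x$A[[x$levels]])
  ))
  invisible(x)
}

#' @describeIn multilevel_dwt Tidy the coefficient pyramid into a long tibble
#'   with columns `level`, `type` (`"A"`/`"D"`), `k` and `value`.
#' @param x A `wavelet_decomposition`.
#' @param ... Unused.
#' @method tidy wavelet_decomposition
#' @export
tidy.wavelet_decomposition <- function(x, ...) {
  purrr::map_dfr(seq_len(x$levels), function(i) {
    dplyr::bind_rows(
      tibble::tibble(level = i, type = "A", k = seq_along(x$A[[i]]),
                     value = x$A[[i]]),
      tibble::tibble(level = i, type = "D", k = seq_along(x$D[[i]]),
                     value = x$D[[i]])
    )
  })
}
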