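#' First difference of a series
#'
#' `y[k] = x[k + 1] - x[k]`, the integer-order difference used to convert a
#' unit-root (non-stationary) acceleration signal into a stationary series
#' before ARFIMA modelling.
#'
#' @param x Numeric vector of length >= 2.
#' @return Numeric vector of length `length(x) - 1`.
#' @examples
#' first_difference(c(1, 3, 6, 10))  # 2 3 4
#' @export
first_difference <- function(x) {
  check_numeric(x, "x", min_len = 2L)
  diff(x)
}

#' Fractional-differencing binomial weights
#'
#' Weights of the truncated binomial expansion of `(1 - L)^d` for real `d`:
#' `w[0] = 1`, `w[l] = w[l - 1] * (l - 1 - d) / l`, the recursive form of the
#' Gamma-function ratios `(-1)^l Gamma(d + 1) / (Gamma(l + 1) Gamma(d + 1 - l))`.
#'
#' @param d Real differencing order.
#' @param n Number of weights to return (lags `0 .. n - 1`).
#' @return Numeric vector of length `n`.
#' @export
frac_diff_weights <- function(d, n) {
  if (!is.finite(d)) abort("`d` must be finite.")
  n <- as.integer(n)
  if (n < 1L) abort("`n` must be >= 1.")
  w <- numeric(n)
  w[1] <- 1
  if (n > 1L) {
    for (l in seq_len(n - 1L)) w[l + 1L] <- w[l] * (l - 1 - d) / l
  }
  w
}

#' Apply the fractional difference operator
#'
#' Filters `x` with the truncated binomial expansion of `(1 - L)^d`. With
#' `d = 0` this is the identity; with `d = 1` it reproduces the first
#' difference (after the first sample); negative `d` fractionally
#' *integrates*. The default truncation is the series length, which is exact
#' for a finite sample.
#'
#' @param x Numeric vector.
#' @param d Real differencing order.
#' @param truncation Highest lag retained in the expansion (default
#'   `length(x)`, i.e. no truncation for a finite sample).
#' @return Numeric vector of `length(x)` filtered values (output `t` uses
#'   samples `1..t` only).
#' @examples
#' fractional_difference(c(1, 3, 6, 10), d = 1)[-1]  # 2 3 4
#' @export
fractional_difference <- function(x, d, truncation = length(x)) {
  check_numeric(x, "x")
  truncation <- max(1L, as.integer(truncation))
  n <- length(x)
  w <- frac_diff_weights(d, min(n, truncation + 1L))
  # y[t] = sum_l w[l] x[t - l]; FFT convolution keeps the grid fit cheap
  if (n > 256L) {
    y <- stats::convolve(x, rev(w), type = "open")[seq_len(n)]
  } else {
    y <- as.vector(stats::filter(c(rep(0, length(w) - 1L), x), w,
                                 method = "convolution", sides = 1L))
    y <- y[-seq_len(length(w) - 1L)]
  }
  y
}

#' Fit an ARFIMA(r, d, q) model by profile likelihood
#'
#' Two-stage estimator for a stationary series: the fractional order `d` is
#' profiled over `[-0.5, 0.5]` (coarse grid by conditional-sum-of-squares
#' likelihood, then a golden-section refinement, finally an exact-ML polish
#' in a narrow bracket), and at each candidate `d` the fractionally
#' differenced series is fitted with a Gaussian ARMA(r, q) maximum-likelihood
#' fit ([stats::arima()]). The series is demeaned before differencing.
#'
#' `AIC = 2k - 2 logLik` with `k = r + q + 2` (the fractional order and the
#' innovation variance are counted; this convention is frozen here).
#'
#' @param x Numeric stationary series, length >= 64.
#' @param r,q Non-negative AR and MA orders (each <= 4).
#' @param d_range Search interval for `d` (default `c(-0.5, 0.5)`).
#' @return An object of class `arfima_fit`: list with `r`, `q`, `d`, `ar`,
#'   `ma`, `mean`, `sigma2`, `loglik`, `aic`, `n`, `converged`.
#' @examples
#' \donttest{
#' s <- gen_arfima_series(512, d = 0.3, ar = 0.5, seed = 1)
#' fit_arfima(s, r = 1, q = 0)$d
#' }
#' @export
fit_arfima <- function(x, r = 0L, q = 0L, d_range = c(-0.5, 0.5)) {
  check_numeric(x, "x", min_len = 64L)
  r <- as.integer(r); q <- as.integer(q)
  if (r < 0L || r > 4L || q < 0L || q > 4L) {
    abort("`r` and `q` must be integers in [0, 4].")
  }
  mu <- mean(x)
  xc <- x - mu
  fit_at <- function(d, method) {
    z <- fractional_difference(xc, d)
    tryCatch(
      suppressWarnings(arima(z, order = c(r, 0L, q), include.mean = FALSE,
                             method = method)),
      error = function(e) NULL
    )
  }
  nll <- function(d, method) {
    f <- fit_at(d, method)
    if (is.null(f) || !is.finite(f$loglik)) return(1e10)
    -f$loglik
  }
  grid <- seq(d_range[1] + 0.05, d_range[2] - 0.05, by = 0.1)
  vals <- vapply(grid, nll, numeric(1), method = "CSS")
  if (all(vals >= 1e10)) {
    return(structure(list(r = r, q = q, d = NA_real_, converged = FALSE),
                     class = "arfima_fit"))
  }
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(nll, c(lo, hi), method = "CSS", tol = 5e-3)
  bracket <- c(max(d_range[1], opt$minimum - 0.06),
               min(d_range[2], opt$minimum + 0.06))
  opt2 <- optimize(nll, bracket, method = "CSS-ML", tol = 2e-3)
  d_hat <- opt2$minimum
  final <- fit_at(d_hat, "CSS-ML")
  if (is.null(final)) final <- fit_at(d_hat, "CSS")
  if (is.null(final)) {
    return(structure(list(r = r, q = q, d = NA_real_, converged = FALSE),
                     class = "arfima_fit"))
  }
  co <- stats::coef(final)
  k <- r + q + 2
  ll <- as.numeric(final$loglik)
  structure(
    list(
      r = r, q = q, d = d_hat,
      ar = if (r > 0) unname(co[paste0("ar", seq_len(r))]) else numeric(),
      ma = if (q > 0) unname(co[paste0("ma", seq_len(q))]) else numeric(),
      mean = mu,
      sigma2 = final$sigma2,
      loglik = ll,
      aic = 2 * k - 2 * ll,
      n = length(x),
      converged = TRUE
    ),
    class = "arfima_fit"
  )
}

#' @export
print.arfima_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat(sprintf("<arfima_fit> ARFIMA(%d, d, %d): did not converge\n", x$r, x$q))
    return(invisible(x))
  }
  cat(sprintf(
    "<arfima_fit> ARFIMA(%d, %.3f, %d), logLik = %.2f, AIC = %.2f\n",
    x$r, x$d, x$q, x$loglik, x$aic
  ))
  invisible(x)
}

#' @describeIn fit_arfima Coefficients as a tibble (`term`, `estimate`).
#' @param x An `arfima_fit`.
#' @param ... Unused.
#' @method tidy arfima_fit
#' @export
tidy.arfima_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(
    term = c("d", if (x$r > 0) paste0("ar", seq_len(x$r)),
             if (x$q > 0) paste0("ma", seq_len(x$q)), "mean", "sigma2"),
    estimate = c(x$d, x$ar, x$ma, x$mean, x$sigma2)
  )
}

#' @describeIn fit_arfima One-row fit summary (`r`, `q`, `d`, `loglik`,
#'   `aic`, `sigma2`, `n`, `converged`).
#' @method glance arfima_fit
#' @export
glance.arfima_fit <- function(x, ...) {
  tibble::tibble(
    r = x$r, q = x$q, d = if (isTRUE(x$converged)) x$d else NA_real_,
    loglik = if (isTRUE(x$converged)) x$loglik else NA_real_,
    aic = if (isTRUE(x$converged)) x$aic else NA_real_,
    sigma2 = if (isTRUE(x$converged)) x$sigma2 else NA_real_,
    n = if (!is.null(x$n)) x$n else NA_integer_,
    converged = isTRUE(x$converged)
  )
}

#' Grid search over ARFIMA orders
#'
#' Fits every `(r, q)` combination up to the given maxima with
#' [fit_arfima()], drops non-convergent fits, and returns the model with the
#' smallest AIC. Ties are broken by smaller `r + q`, then smaller `r`
#' (parsimony first).
#'
#' @param x Numeric stationary series, length >= 64.
#' @param r_max,q_max Largest AR and MA orders to try (default 4, giving a
#'   5 x 5 = 25-model grid).
#' @return The winning `arfima_fit`, with the full grid attached as a tibble
#'   in `$grid` (columns `r`, `q`, `d`, `loglik`, `aic`, `converged`).
#' @export
select_arfima <- function(x, r_max = 4L, q_max = 4L) {
  check_numeric(x, "x", min_len = 64L)
  combos <- expand.grid(r = 0:r_max, q = 0:q_max)
  fits <- purrr::pmap(combos, function(r, q) fit_arfima(x, r, q))
  grid <- purrr::map_dfr(fits, glance)
  ok <- which(grid$converged)
  if (!length(ok)) abort("no ARFIMA model on the grid converged.")
  sub <- grid[ok, ]
  ord <- order(sub$aic, sub$r + sub$q, sub$r)
  best <- fits[[ok[ord[1]]]]
  best$grid <- grid
  best
}

#' Fractal parameters of the original non-stationary process
#'
#' Converts the fractional order estimated on a first-differenced
#' (stationary) series back to the parameters of the original non-stationary
#' signal: `d_tilde = d + 1`, `beta = 2 d_tilde`, `H = (beta - 1)/2 =
#' d_tilde - 0.5`, and `fd = 2 - H`. The chain is affine, so equivalently
#' `fd = 1.5 - d`.
#'
#' @param d Fractional order of the stationary (differenced) series,
#'   normally in `[-0.5, 0.5]`. Vectorized.
#' @param d_tilde Alternatively, the fractional-integration order of the
#'   non-stationary process itself (`d + 1`); supply exactly one of the two.
#' @return A tibble with columns `d`, `d_tilde`, `beta`, `hurst`, `fd`.
#' @examples
#' nonstationary_fractal_params(d = 0.49)       # H = 0.99, fd = 1.01
#' nonstationary_fractal_params(d_tilde = 0.518)  # walking: fd = 1.982
#' @export
nonstationary_fractal_params <- function(d = NULL, d_tilde = NULL) {
  if (is.null(d) == is.null(d_tilde)) {
    abort("supply exactly one of `d` or `d_tilde`.")
  }
  if (is.null(d)) {
    check_numeric(d_tilde, "d_tilde")
    d <- d_tilde - 1
  } else {
    check_numeric(d, "d")
    d_tilde <- d + 1
  }
  beta <- 2 * d_tilde
  h <- hurst_from_beta(beta)
  tibble::tibble(d = d, d_tilde = d_tilde, beta = beta, hurst = h,
                 fd = fd_from_hurst(h))
}
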