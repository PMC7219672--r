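#' Schwert maximum-lag rule
#'
#' `floor(12 * (n/100)^(1/4))`, the standard upper bound on the augmented
#' lag order of an ADF regression for a series of `n` samples.
#'
#' @param n Number of samples (>= 8).
#' @return Integer maximum lag.
#' @examples
#' schwert_max_lag(100)  # 12
#' schwert_max_lag(1600)  # 24
#' @export
schwert_max_lag <- function(n) {
  if (n < 8) abort("`n` must be >= 8.")
  as.integer(floor(12 * (n / 100)^0.25))
}

#' KPSS maximum-lag rule
#'
#' `floor(sqrt(n))`, the square-root bandwidth rule for the long-run
#' variance estimator of the KPSS statistic.
#'
#' @param n Number of samples (>= 8).
#' @return Integer lag truncation.
#' @examples
#' kpss_max_lag(128)  # 11
#' @export
kpss_max_lag <- function(n) {
  if (n < 8) abort("`n` must be >= 8.")
  as.integer(floor(sqrt(n)))
}

# finite-sample quantiles of the Dickey-Fuller tau_mu distribution
# (constant, no trend), indexed by sample size; standard published table
.adf_tab <- list(
  probs = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
  n = c(25, 50, 100, 250, 500, 1e5),
  cv = rbind(
    c(-3.75, -3.33, -3.00, -2.63, -0.37, 0.00, 0.34, 0.72),
    c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66),
    c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63),
    c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62),
    c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61),
    c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60)
  )
)

.adf_pvalue <- function(stat, n) {
  tab <- .adf_tab
  cv <- vapply(seq_along(tab$probs), function(j) {
    stats::approx(1 / tab$n, tab$cv[, j], xout = 1 / n, rule = 2)$y
  }, numeric(1))
  stats::approx(cv, tab$probs, xout = stat, rule = 2)$y
}

# one ADF regression: delta x_t on intercept, x_{t-1}, p lagged differences;
# returns the unit-root t statistic plus pieces the lag rules need
.adf_reg <- function(x, p, n_common = NULL) {
  dx <- diff(x)
  n <- length(dx)
  start <- if (is.null(n_common)) p + 1L else n_common + 1L
  idx <- start:n
  y <- dx[idx]
  X <- cbind(intercept = 1, ylag = x[idx])
  if (p > 0L) {
    lags <- vapply(seq_len(p), function(j) dx[idx - j], numeric(length(idx)))
    X <- cbind(X, lags)
  }
  fit <- lm.fit(X, y)
  res <- fit$residuals
  k <- ncol(X)
  df <- length(y) - k
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * diag(XtXinv))
  tstats <- fit$coefficients / se
  list(
    stat = tstats[2L],
    t_last = if (p > 0L) tstats[k] else NA_real_,
    aic = length(y) * log(sum(res^2) / length(y)) + 2 * k,
    nobs = length(y)
  )
}

#' Augmented Dickey-Fuller test (constant, no trend)
#'
#' Tests the unit-root null against a stationary alternative with a
#' constant-only ADF regression. Rejection (p < alpha) means the series is
#' judged stationary. Lag order is chosen by one of:
#' \describe{
#'   \item{`"schwert-ng"`}{sequential rule: start at [schwert_max_lag()],
#'     keep the order if the last lag's |t|-statistic exceeds 1.6, otherwise
#'     drop one lag and repeat.}
#'   \item{`"aic"`}{minimize the regression AIC over `0..pmax` on a common
#'     estimation sample.}
#'   \item{`"fixed"`}{use `lags` as given.}
#' }
#'
#' @param x Numeric series, length >= 32.
#' @param lag_rule One of `"schwert-ng"`, `"aic"`, `"fixed"`.
#' @param lags Lag order for `lag_rule = "fixed"`.
#' @param alpha Decision level (default 0.05).
#' @return A one-row tibble: `test`, `lag_used`, `statistic`, `p_value`,
#'   `reject_null`, `stationary`, `alpha`, `lag_rule`. `reject_null = TRUE`
#'   means the unit root is rejected, i.e. the series looks stationary.
#' @export
adf_test <- function(x, lag_rule = c("schwert-ng", "aic", "fixed"),
                     lags = NULL, alpha = 0.05) {
  lag_rule <- match.arg(lag_rule)
  check_numeric(x, "x", min_len = 32L)
  if (sd(x) == 0) abort("`x` is constant; the ADF regression is degenerate.")
  n <- length(x)
  pmax <- min(schwert_max_lag(n), n %/% 4L)
  p <- switch(lag_rule,
    "schwert-ng" = {
      p_sel <- 0L
      for (pc in seq(pmax, 1L)) {
        r <- .adf_reg(x, pc)
        if (is.finite(r$t_last) && abs(r$t_last) > 1.6) { p_sel <- pc; break }
      }
      p_sel
    },
    "aic" = {
      aics <- vapply(0:pmax, function(pc) .adf_reg(x, pc, n_common = pmax)$aic,
                     numeric(1))
      (0:pmax)[which.min(aics)]
    },
    "fixed" = {
      if (is.null(lags)) abort("`lags` required when lag_rule = \"fixed\".")
      as.integer(lags)
    }
  )
  r <- .adf_reg(x, p)
  pval <- .adf_pvalue(r$stat, r$nobs)
  reject <- pval < alpha
  tibble::tibble(
    test = "ADF", lag_used = p, statistic = unname(r$stat), p_value = pval,
    reject_null = reject, stationary = reject, alpha = alpha,
    lag_rule = lag_rule
  )
}

# interpolation table for the level-stationarity KPSS statistic
.kpss_tab <- list(cv = c(0.347, 0.463, 0.574, 0.739),
                  probs = c(0.10, 0.05, 0.025, 0.01))

#' KPSS level-stationarity test
#'
#' Tests the null of level stationarity against a unit-root alternative:
#' the statistic is the scaled cumulative sum of demeaned values with a
#' Bartlett-kernel (Newey-West) long-run variance at the given lag
#' truncation. Rejection (p < alpha) means the series is judged
#' non-stationary — the mirror image of the ADF decision, giving the two
#' tests together a double-validation verdict.
#'
#' @param x Numeric series, length >= 32.
#' @param lags Lag truncation for the long-run variance. The default is the
#'   short Newey-West rule `floor(4 * (n/100)^(1/4))` -- the test is run
#'   with few lags and [kpss_max_lag()] bounds how far the sensitivity mode
#'   may extend the bandwidth.
#' @param alpha Decision level (default 0.05).
#' @param sensitivity If `TRUE`, re-run at `lags + 2` and `lags + 4`
#'   (capped at [kpss_max_lag()]) and return one row per lag choice.
#' @return A tibble (one row per lag tried): `test`, `lag_used`,
#'   `statistic`, `p_value`, `reject_null`, `stationary`, `alpha`,
#'   `lag_rule`. Here `reject_null = TRUE` means *non*-stationary, so
#'   `stationary = !reject_null`.
#' @export
kpss_test <- function(x, lags = NULL, alpha = 0.05, sensitivity = FALSE) {
  check_numeric(x, "x", min_len = 32L)
  if (sd(x) == 0) abort("`x` is constant; the KPSS statistic is degenerate.")
  n <- length(x)
  base_lag <- if (is.null(lags)) {
    as.integer(floor(4 * (n / 100)^0.25))
  } else {
    as.integer(lags)
  }
  lag_set <- if (sensitivity) {
    pmin(base_lag + c(0L, 2L, 4L), kpss_max_lag(n))
  } else {
    base_lag
  }
  rule <- if (is.null(lags)) "newey-west" else "fixed"
  purrr::map_dfr(lag_set, function(L) {
    e <- x - mean(x)
    S <- cumsum(e)
    lrv <- sum(e^2) / n
    if (L > 0L) {
      for (l in seq_len(L)) {
        w <- 1 - l / (L + 1)
        lrv <- lrv + 2 * w * sum(e[1:(n - l)] * e[(l + 1):n]) / n
      }
    }
    stat <- sum(S^2) / (n^2 * lrv)
    pval <- stats::approx(.kpss_tab$cv, .kpss_tab$probs, xout = stat,
                          rule = 2)$y
    reject <- pval < alpha
    tibble::tibble(
      test = "KPSS", lag_used = L, statistic = stat, p_value = pval,
      reject_null = reject, stationary = !reject, alpha = alpha,
      lag_rule = rule
    )
  })
}

#' Stationarity battery over a set of windows
#'
#' Runs the ADF and KPSS tests on each zero-meaned window and on its first
#' difference, and combines them into a per-series verdict:
#' "non-stationary" when the ADF fails to reject its unit-root null *and*
#' KPSS rejects stationarity; "stationary" when the ADF rejects and KPSS
#' does not; anything else is "inconclusive".
#'
#' @param windows Windows to test: the tibble returned by
#'   [segment_windows()] (list-column `samples`), a plain list of numeric
#'   vectors, or a list of [windowed_signal()] objects.
#' @param alpha Decision level for both tests.
#' @param lag_rule ADF lag rule, see [adf_test()].
#' @return A tibble with one row per window and series form (`"raw"` /
#'   `"diff"`): `window`, `series`, `adf_p`, `adf_stationary`, `kpss_p`,
#'   `kpss_stationary`, `verdict`.
#' @export
stationarity_battery <- function(windows, alpha = 0.05,
                                 lag_rule = "schwert-ng") {
  sigs <- if (is.data.frame(windows)) {
    if (!"samples" %in% names(windows)) {
      abort("`windows` data frame must have a `samples` list-column.")
    }
    windows$samples
  } else if (is.list(windows)) {
    lapply(windows, function(w) if (inherits(w, "windowed_signal")) w$a else w)
  } else {
    abort("`windows` must be a data frame or a list.")
  }
  if (!length(sigs)) {
    return(tibble::tibble(
      window = integer(), series = character(), adf_p = numeric(),
      adf_stationary = logical(), kpss_p = numeric(),
      kpss_stationary = logical(), verdict = character()
    ))
  }
  purrr::imap_dfr(sigs, function(w, i) {
    a <- w - mean(w)
    purrr::map_dfr(list(raw = a, diff = first_difference(a)), function(s) {
      adf <- adf_test(s, lag_rule = lag_rule, alpha = alpha)
      kps <- kpss_test(s, alpha = alpha)
      verdict <- if (!adf$stationary && !kps$stationary) {
        "non-stationary"
      } else if (adf$stationary && kps$stationary) {
        "stationary"
      } else {
        "inconclusive"
      }
      tibble::tibble(
        adf_p = adf$p_value, adf_stationary = adf$stationary,
        kpss_p = kps$p_value, kpss_stationary = kps$stationary,
        verdict = verdict
      )
    }, .id = "series") |>
      dplyr::mutate(window = as.integer(i), .before = 1)
  })
}
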