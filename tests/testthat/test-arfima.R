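test_that("first difference matches hand arithmetic", {
  expect_equal(first_difference(c(1, 3, 6, 10)), c(2, 3, 4))
  expect_equal(first_difference(rep(5, 10)), rep(0, 9))
  expect_error(first_difference(1), "at least 2")
})

test_that("differencing a random walk restores stationarity", {
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    walk <- cumsum(rnorm(512))
    adf_test(first_difference(walk))$stationary
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("binomial weights match the direct product-form oracle", {
  for (d in c(0.4, -0.3, 1, 0.49)) {
    w <- frac_diff_weights(d, 12)
    # independent oracle: w_l = (-1)^l * prod_{j<l}(d - j) / l!
    oracle <- vapply(0:11, function(l) {
      if (l == 0) return(1)
      (-1)^l * prod(d - 0:(l - 1)) / factorial(l)
    }, numeric(1))
    expect_equal(w, oracle, tolerance = 1e-12)
  }
})

test_that("fractional differencing generalizes the integer cases", {
  x <- fixture_window(2, 64)
  expect_equal(fractional_difference(x, 0), x)
  expect_equal(fractional_difference(x, 1)[-1], first_difference(x),
               tolerance = 1e-12)
  # impulse response equals the weight sequence
  delta <- c(1, rep(0, 31))
  expect_equal(fractional_difference(delta, 0.4), frac_diff_weights(0.4, 32),
               tolerance = 1e-12)
})

test_that("fractional differencing is invertible on the interior", {
  x <- sin(seq(0, 6 * pi, length.out = 256)) + 0.5
  for (d in c(0.2, 0.4, -0.4)) {
    y <- fractional_difference(fractional_difference(x, d), -d)
    keep <- 64:256  # truncation-limited interior
    expect_lt(max(abs(y[keep] - x[keep])), 1e-6)
  }
})

test_that("profile fit recovers d for white noise", {
  dhat <- vapply(1:5, function(s) {
    set.seed(400 + s)
    fit_arfima(rnorm(2048), 0, 0)$d
  }, numeric(1))
  expect_lt(abs(mean(dhat)), 0.1)
})

test_that("profile fit recovers d for an ARFIMA(1, 0.3, 1) process", {
  dhat <- vapply(1:5, function(s) {
    s_series <- gen_arfima_series(2048, d = 0.3, ar = 0.5, ma = 0.3,
                                  seed = 500 + s)
    fit_arfima(s_series, 1, 1)$d
  }, numeric(1))
  expect_lt(abs(mean(dhat) - 0.3), 0.1)
})

test_that("fit reports the frozen AIC convention and model structure", {
  s <- gen_arfima_series(512, d = 0.2, ar = 0.4, seed = 9)
  f <- fit_arfima(s, 1, 0)
  expect_s3_class(f, "arfima_fit")
  expect_equal(f$aic, 2 * (1 + 0 + 2) - 2 * f$loglik)
  expect_length(f$ar, 1)
  expect_length(f$ma, 0)
  td <- tidy(f)
  expect_setequal(td$term, c("d", "ar1", "mean", "sigma2"))
  expect_error(fit_arfima(rnorm(32), 0, 0), "at least 64")
  expect_error(fit_arfima(rnorm(128), 5, 0), "\\[0, 4\\]")
})

test_that("AIC rejects underfitting when ARMA structure is present", {
  wins <- vapply(1:5, function(s) {
    s_series <- gen_arfima_series(2048, d = 0.3, ar = 0.5, ma = 0.3,
                                  seed = 820 + s)
    fit_arfima(s_series, 1, 1)$aic <= fit_arfima(s_series, 0, 0)$aic
  }, logical(1))
  expect_true(all(wins))
})

test_that("AIC keeps white-noise overfitting in check", {
  # on a structureless series the 2k penalty usually outweighs the
  # overfitted model's likelihood gain
  wins <- vapply(1:12, function(s) {
    set.seed(800 + s)
    x <- rnorm(1024)
    fit_arfima(x, 0, 0)$aic <= fit_arfima(x, 2, 2)$aic
  }, logical(1))
  expect_gte(mean(wins), 0.6)
})

test_that("grid selection favours parsimony on a structureless series", {
  picks <- vapply(1:4, function(s) {
    set.seed(840 + s)
    best <- select_arfima(rnorm(768), r_max = 2, q_max = 2)
    best$r + best$q
  }, numeric(1))
  expect_gte(mean(picks <= 2), 3 / 4)
  s_series <- gen_arfima_series(512, d = 0.2, seed = 7)
  best <- select_arfima(s_series, r_max = 1, q_max = 1)
  expect_equal(nrow(best$grid), 4L)
  expect_true(all(c("r", "q", "d", "aic") %in% names(best$grid)))
  expect_error(select_arfima(rnorm(32)), "at least 64")
})

test_that("stationary-to-nonstationary conversion reproduces printed rows", {
  # falls row: d = 0.49 -> H = 0.99, fd = 1.01
  falls <- nonstationary_fractal_params(d = 0.49)
  expect_equal(falls$d_tilde, 1.49)
  expect_equal(falls$hurst, 0.99)
  expect_equal(falls$fd, 1.01)
  # walking row given as the non-stationary order directly
  walking <- nonstationary_fractal_params(d_tilde = 0.518)
  expect_equal(walking$fd, 1.982)
  # boundary arithmetic
  edge <- nonstationary_fractal_params(d = -0.5)
  expect_equal(edge$d_tilde, 0.5)
  expect_equal(edge$beta, 1)
  expect_equal(edge$hurst, 0)
  expect_equal(edge$fd, 2)
})

test_that("the conversion chain is affine: fd = 1.5 - d", {
  set.seed(12)
  d <- runif(100, -0.5, 0.5)
  out <- nonstationary_fractal_params(d = d)
  expect_equal(out$fd, 1.5 - d, tolerance = 1e-12)
  expect_error(nonstationary_fractal_params(), "exactly one")
  expect_error(nonstationary_fractal_params(d = 0.1, d_tilde = 1.1),
               "exactly one")
})
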