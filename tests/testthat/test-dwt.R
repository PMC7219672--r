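test_that("db4 filter pair satisfies the orthonormal filter invariants", {
  f <- db4_filters()
  expect_equal(sum(f$h), sqrt(2), tolerance = 1e-12)
  expect_equal(sum(f$g), 0, tolerance = 1e-12)
  expect_equal(sum(f$h^2), 1, tolerance = 1e-12)
  expect_equal(sum(f$g^2), 1, tolerance = 1e-12)
  # quadrature mirror relation g[k] = (-1)^k h[7-k] (0-based)
  expect_equal(f$g, (-1)^(0:7) * rev(f$h), tolerance = 1e-15)
  # double-shift orthogonality of the lowpass filter
  expect_equal(sum(f$h[1:6] * f$h[3:8]), 0, tolerance = 1e-12)
  expect_equal(sum(f$h[1:4] * f$h[5:8]), 0, tolerance = 1e-12)
})

test_that("periodic extension wraps the signal", {
  x <- 1:8
  ext <- periodic_extend(x, taps = 8)
  expect_length(ext, 8 + 8 - 2)
  expect_true(all(ext %in% x))
  expect_equal(ext, c(3:8, 1:8))

  expect_equal(periodic_extend(rep(2, 16)), rep(2, 22))
  expect_error(periodic_extend(1:4, taps = 8), "as long as")
})

test_that("reference level transform matches a brute-force oracle", {
  # triple-loop circular convolution oracle, independent of the package path
  oracle <- function(x, f) {
    n <- length(x)
    y <- numeric(n)
    for (nn in 0:(n - 1)) {
      acc <- 0
      for (m in 0:7) acc <- acc + f[m + 1] * x[((nn - m) %% n) + 1]
      y[nn + 1] <- acc
    }
    y[seq(2, n, by = 2)]
  }
  f <- db4_filters()
  delta <- c(1, rep(0, 15))
  r <- dwt_level_reference(delta, f)
  expect_equal(r$A, oracle(delta, f$h), tolerance = 1e-14)
  expect_equal(r$D, oracle(delta, f$g), tolerance = 1e-14)

  set.seed(21)
  x <- rnorm(32)
  r <- dwt_level_reference(x, f)
  expect_equal(r$A, oracle(x, f$h), tolerance = 1e-12)
  expect_equal(r$D, oracle(x, f$g), tolerance = 1e-12)
})

test_that("constant signals map to zero details and scaled approximations", {
  r <- dwt_level_reference(rep(3, 16))
  expect_equal(r$D, rep(0, 8), tolerance = 1e-12)
  expect_equal(r$A, rep(3 * sqrt(2), 8), tolerance = 1e-12)
})

test_that("fused transform equals the reference on random inputs", {
  set.seed(33)
  for (n in c(16L, 32L, 128L)) {
    for (i in 1:50) {
      x <- rnorm(n)
      r <- dwt_level_reference(x)
      fu <- dwt_level_fused(x)
      expect_lt(max(abs(r$A - fu$A)), 1e-12)
      expect_lt(max(abs(r$D - fu$D)), 1e-12)
    }
  }
})

test_that("single-level transform conserves energy", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(64)
    r <- dwt_level_fused(x)
    expect_equal(sum(r$A^2) + sum(r$D^2), sum(x^2), tolerance = 1e-9)
  }
})

test_that("multi-level decomposition halves lengths and telescopes energy", {
  set.seed(6)
  x <- rnorm(128)
  dec <- multilevel_dwt(x, levels = 4)
  expect_equal(lengths(dec$A), c(64L, 32L, 16L, 8L))
  expect_equal(lengths(dec$D), c(64L, 32L, 16L, 8L))
  total <- sum(dec$A[[4]]^2) + sum(unlist(dec$D)^2)
  expect_equal(total, sum(x^2), tolerance = 1e-9)

  const <- multilevel_dwt(rep(2, 128))
  for (i in 1:4) expect_equal(const$D[[i]], rep(0, 128 / 2^i),
                              tolerance = 1e-12)
  expect_equal(const$A[[4]], rep(2 * 4, 8), tolerance = 1e-12)

  expect_error(multilevel_dwt(rnorm(100), levels = 4), "divisible")
})

test_that("reference and fused agree across full multi-level pyramids", {
  set.seed(7)
  x <- rnorm(128)
  a <- multilevel_dwt(x, method = "reference")
  b <- multilevel_dwt(x, method = "fused")
  for (i in 1:4) {
    expect_lt(max(abs(a$A[[i]] - b$A[[i]])), 1e-12)
    expect_lt(max(abs(a$D[[i]] - b$D[[i]])), 1e-12)
  }
})

test_that("transform matches an independent periodized DWT implementation", {
  # PyWavelets oracle: with this package's analysis orientation, the level-1
  # coefficients equal pywt.dwt(roll(x, -1), "db4", "periodization") up to a
  # frozen circular shift of 2 (N = 16) and a sign flip on the details
  set.seed(9)
  x <- rnorm(16)
  r <- dwt_level_reference(x)
  tf <- tempfile(fileext = ".txt")
  writeLines(format(x, digits = 17), tf)
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import numpy as np, pywt, sys",
    "x = np.loadtxt(sys.argv[1])",
    "cA, cD = pywt.dwt(np.roll(x, -1), 'db4', mode='periodization')",
    "out = np.concatenate([np.roll(cA, 2), -np.roll(cD, 2)])",
    "for v in out:",
    "    print(float(v))"
  ), py)
  res <- suppressWarnings(system2("python", c(py, tf), stdout = TRUE))
  skip_if(length(res) != 16, "python/pywt oracle unavailable")
  ref <- as.numeric(res)
  expect_equal(r$A, ref[1:8], tolerance = 1e-10)
  expect_equal(r$D, ref[9:16], tolerance = 1e-10)
})

test_that("tidied decomposition is long and complete", {
  dec <- multilevel_dwt(rnorm(128))
  td <- tidy(dec)
  expect_equal(nrow(td), 2 * (64 + 32 + 16 + 8))
  expect_setequal(unique(td$type), c("A", "D"))
})
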