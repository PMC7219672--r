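test_that("assembled feature vector has the frozen 14-dimensional layout", {
  w <- windowed_signal(fixture_window(1))
  dec <- multilevel_dwt(w$a)
  fv <- assemble_features(w, dec)
  expect_equal(
    names(fv),
    c(paste0("a4_", 1:8), "mu", "var", "sd", paste0("fd", 1:4),
      "fd_undefined")
  )
  expect_length(feature_columns("full"), 14)
  expect_no_na(as.numeric(fv[feature_columns("full")]))
  expect_false(fv$fd_undefined)
  expect_equal(fv$sd, sqrt(fv$var))
})

test_that("constant windows propagate sentinel fractal dimensions", {
  w <- windowed_signal(rep(3, 128))
  dec <- multilevel_dwt(w$a)
  fv <- assemble_features(w, dec)
  expect_equal(as.numeric(fv[paste0("a4_", 1:8)]), rep(0, 8),
               tolerance = 1e-12)  # zero-mean of a constant is zero
  expect_equal(fv$mu, 3)
  expect_equal(as.numeric(fv[paste0("fd", 1:4)]), rep(2, 4))
  expect_true(fv$fd_undefined)
})

test_that("fall windows carry systematically lower fractal dimensions", {
  feats <- fixture_features()
  fall <- feats[feats$label == "fall", ]
  adl <- feats[feats$label == "adl", ]
  expect_lt(mean(fall$fd1), mean(adl$fd1))
  expect_lt(mean(fall$fd2), mean(adl$fd2))
})

test_that("LDA separates well-separated Gaussian blobs", {
  set.seed(50)
  n <- 200
  blob <- function(mu, lab) {
    tibble::tibble(x1 = rnorm(n, mu), x2 = rnorm(n, mu), label = lab)
  }
  d <- dplyr::bind_rows(blob(3, "fall"), blob(-3, "adl"))
  m <- fall_lda(d, features = c("x1", "x2"))
  expect_gte(glance(m)$training_accuracy, 0.99)
})

test_that("LDA is at chance on identical class distributions", {
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    d <- tibble::tibble(x1 = rnorm(200), x2 = rnorm(200),
                        label = rep(c("fall", "adl"), 100))
    glance(fall_lda(d, features = c("x1", "x2")))$training_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("LDA weights match the closed-form discriminant direction", {
  set.seed(51)
  n <- 4000
  sds <- c(1, 2, 0.5)
  mu1 <- c(1, 0, -1); mu0 <- c(-1, 1, 0)
  X1 <- sapply(1:3, function(j) rnorm(n, mu1[j], sds[j]))
  X0 <- sapply(1:3, function(j) rnorm(n, mu0[j], sds[j]))
  d <- tibble::as_tibble(as.data.frame(rbind(X1, X0)))
  names(d) <- c("x1", "x2", "x3")
  d$label <- rep(c("fall", "adl"), each = n)
  m <- fall_lda(d, features = c("x1", "x2", "x3"))
  w_true <- (mu1 - mu0) / sds^2          # diagonal-covariance oracle
  cosine <- sum(m$w * w_true) / sqrt(sum(m$w^2) * sum(w_true^2))
  expect_gte(cosine, 0.99)
})

test_that("LDA agrees with an established reference implementation", {
  feats <- fixture_features()
  m <- fall_lda(feats)
  mine <- predict(m, feats)$class
  # MASS warns about collinear level-4 coefficients; expected on this data
  ref <- suppressWarnings(
    MASS::lda(as.matrix(feats[feature_columns("full")]),
              grouping = feats$label)
  )
  ref_class <- as.character(predict(ref)$class)
  ref_class <- ifelse(ref_class == "fall", "fall", "other")
  expect_gt(mean(mine == ref_class), 0.99)
})

test_that("discriminant applies the inclusive fall boundary", {
  set.seed(52)
  d <- tibble::tibble(x1 = c(rnorm(50, 3), rnorm(50, -3)),
                      x2 = c(rnorm(50, 3), rnorm(50, -3)),
                      label = rep(c("fall", "adl"), each = 50))
  m <- fall_lda(d, features = c("x1", "x2"))
  expect_gt(discriminant(m, colMeans(d[d$label == "fall", 1:2])), 0)
  expect_lt(discriminant(m, colMeans(d[d$label == "adl", 1:2])), 0)
  # a point with an exactly-zero score is classified as a fall (inclusive
  # boundary); use a hand-built model so the score is exact in floats
  m0 <- m
  m0$w <- stats::setNames(c(1, 0), c("x1", "x2"))
  m0$b <- 0
  boundary_point <- tibble::tibble(x1 = 0, x2 = 5)
  expect_identical(discriminant(m0, boundary_point), 0)
  expect_equal(predict(m0, boundary_point)$class, "fall")
  expect_error(discriminant(m, c(1, 2, 3)), "dimension mismatch")
})

test_that("predictions are invariant to a common affine feature rescaling", {
  feats <- fixture_features()
  cols <- feature_columns("full")
  m <- fall_lda(feats)
  p0 <- predict(m, feats)$class
  rescaled <- feats
  rescaled[cols] <- rescaled[cols] * 3.7 + 11
  m2 <- fall_lda(rescaled)
  p1 <- predict(m2, rescaled)$class
  expect_equal(p1, p0)
})

test_that("evaluation metrics match hand-computed confusion arithmetic", {
  truth <- rep(c("fall", "fall", "adl"), c(9, 1, 10))
  pred <- c(rep("fall", 9), "adl", rep("adl", 8), "fall", "fall")
  m <- evaluate_predictions(truth, pred)
  expect_equal(m$tp, 9); expect_equal(m$fn, 1)
  expect_equal(m$tn, 8); expect_equal(m$fp, 2)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 9 / 11)

  perfect <- evaluate_predictions(rep("fall", 5), rep("fall", 5))
  expect_equal(perfect$accuracy, 1)
  none <- evaluate_predictions(rep("adl", 5), rep("adl", 5))
  expect_true(is.na(none$sensitivity))
  expect_error(evaluate_predictions("fall", c("fall", "adl")),
               "equal length")
})

test_that("training requires both classes", {
  feats <- fixture_features()
  expect_error(fall_lda(feats[feats$label == "fall", ]), "both classes")
})

test_that("stratified cross-validation covers every window once", {
  feats <- fixture_features()
  cv <- crossval_lda(feats, folds = 5, seed = 3)
  expect_equal(nrow(cv), 5L)
  expect_equal(sum(cv$n_test), nrow(feats))
  expect_true(all(cv$accuracy > 0.5))
})

test_that("model JSON round-trip preserves predictions", {
  feats <- fixture_features()
  m <- fall_lda(feats)
  path <- tempfile(fileext = ".json")
  write_lda_json(m, path)
  m2 <- read_lda_json(path)
  expect_equal(m2$w, m$w, tolerance = 1e-12)
  expect_equal(m2$b, m$b, tolerance = 1e-12)
  expect_equal(predict(m2, feats), predict(m, feats), tolerance = 1e-12)
})
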