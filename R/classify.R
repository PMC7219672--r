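#' Canonical feature column order
#'
#' The classifier consumes a fixed 14-dimensional vector per window:
#' the eight level-4 wavelet approximations, the sum-vector mean and
#' variance (or SD), and the four per-level fractal dimensions.
#'
#' @param set Which subset: `"full"` (all 14), `"fractal"` (fd1..fd4),
#'   `"fractal_a4"` (fd + A4), or `"a4"` (A4 only).
#' @param use_sd If `TRUE` the spread feature is the standard deviation
#'   column `sd` instead of the variance column `var`.
#' @return Character vector of column names.
#' @export
feature_columns <- function(set = c("full", "fractal", "fractal_a4", "a4"),
                            use_sd = FALSE) {
  set <- match.arg(set)
  a4 <- paste0("a4_", 1:8)
  fd <- paste0("fd", 1:4)
  spread <- if (use_sd) "sd" else "var"
  switch(set,
    full = c(a4, "mu", spread, fd),
    fractal = fd,
    fractal_a4 = c(fd, a4),
    a4 = a4
  )
}

# sentinel written into undefined fd slots: the fd of an uncorrelated signal
# would be 1.5, but a *degenerate* (zero-detail-variance) window is flagged
# with 2.0 so the classifier sees it as maximally irregular-unknown
.fd_sentinel <- 2.0

#' Assemble the classifier feature vector for one window
#'
#' Concatenates, in frozen order, the eight level-4 approximations, the
#' sum-vector mean and variance, and the four per-level fractal dimensions
#' of a 128-sample window. Undefined fractal dimensions (degenerate detail
#' variance) are replaced by the sentinel value 2.0 and flagged.
#'
#' @param win A [windowed_signal()] built from the sum-vector window.
#' @param dec The [multilevel_dwt()] decomposition of `win$a` (4 levels).
#' @param frac The [wavelet_fractal_features()] tibble for `dec`; computed
#'   on the fly when `NULL`.
#' @return A one-row tibble with columns `a4_1..a4_8`, `mu`, `var`, `sd`,
#'   `fd1..fd4`, `fd_undefined`.
#' @export
assemble_features <- function(win, dec, frac = NULL) {
  if (!inherits(win, "windowed_signal")) {
    abort("`win` must be a windowed_signal.")
  }
  if (!inherits(dec, "wavelet_decomposition")) {
    abort("`dec` must be a wavelet_decomposition.")
  }
  if (dec$levels != 4L || dec$input_length != win$n) {
    abort("`dec` must be a 4-level decomposition of the window.")
  }
  if (length(dec$A[[4]]) != 8L) {
    abort("level-4 approximations must have length 8 (128-sample window).")
  }
  if (is.null(frac)) {
    frac <- if (win$var_a > 0) {
      wavelet_fractal_features(dec, win$var_a)
    } else {
      tibble::tibble(fd = rep(NA_real_, 4))
    }
  }
  fd <- frac$fd
  undefined <- !is.finite(fd)
  fd[undefined] <- .fd_sentinel
  out <- tibble::as_tibble(c(
    setNames(as.list(dec$A[[4]]), paste0("a4_", 1:8)),
    list(mu = win$mu_a_prime, var = win$var_a_prime,
         sd = sqrt(win$var_a_prime)),
    setNames(as.list(fd), paste0("fd", 1:4))
  ))
  out$fd_undefined <- any(undefined)
  out
}

#' Extract classifier features from accelerometer data
#'
#' The full feature-extraction pipeline: sum-vector magnitude, windowing,
#' zero-meaning, 4-level Daubechies-4 DWT, per-level wavelet-variance
#' fractal dimensions, and assembly of the 14-dimensional feature vector
#' for every window.
#'
#' If `accel` carries a `window_id` column (as the synthetic generator
#' emits), each id is treated as one pre-cut window; otherwise the
#' sum-vector stream is segmented into `window`-sample windows with the
#' given overlap.
#'
#' @param accel Data frame with `ax`, `ay`, `az` (and optionally
#'   `window_id`, `label`).
#' @param window Window length in samples (default 128).
#' @param overlap Window overlap fraction (default 0.5).
#' @param levels DWT levels (default 4).
#' @return A tibble with one row per window: `window_id`, `start_index`,
#'   `label` (if present), the feature columns of [feature_columns()], `sd`,
#'   and `fd_undefined`.
#' @examples
#' d <- gen_labelled_dataset(2, 2, sim_config(seed = 1))
#' extract_features(d)
#' @export
extract_features <- function(accel, window = 128L, overlap = 0.5,
                             levels = 4L) {
  accel <- sum_vector(as_accel(accel))
  if (levels != 4L) abort("the feature vector is defined for 4 DWT levels.")
  one <- function(samples, id, start, label) {
    win <- windowed_signal(samples, start_index = start)
    dec <- multilevel_dwt(win$a, levels = levels)
    feats <- assemble_features(win, dec)
    out <- dplyr::bind_cols(
      tibble::tibble(window_id = id, start_index = start), feats
    )
    if (!is.null(label)) out <- dplyr::mutate(out, label = label, .after = 2)
    out
  }
  if ("window_id" %in% names(accel)) {
    grp <- dplyr::group_split(accel, .data$window_id)
    purrr::map_dfr(grp, function(gr) {
      if (nrow(gr) != window) {
        abort(sprintf("window_id %s has %d samples; expected %d.",
                      gr$window_id[1], nrow(gr), window))
      }
      one(gr$a_sum, as.integer(gr$window_id[1]), 0L,
          if ("label" %in% names(gr)) gr$label[1] else NULL)
    })
  } else {
    segs <- segment_windows(accel$a_sum, n = window, overlap = overlap)
    purrr::imap_dfr(segs$samples, function(s, i) {
      one(s, as.integer(i), segs$start_index[i], NULL)
    })
  }
}

#' Train the two-class linear discriminant fall classifier
#'
#' Pooled-covariance linear discriminant analysis: the weight vector is
#' `w = S^{-1} (mu_fall - mu_other)` with `S` the pooled within-class
#' covariance, and the bias places the boundary midway between the class
#' means shifted by the log prior ratio. When `S` is near singular it is
#' ridge-regularized by `lambda I` with `lambda = 1e-6 trace(S)/p`.
#'
#' @param data Feature tibble including a label column.
#' @param features Character vector of feature columns (default the full
#'   14-dimensional set of [feature_columns()]).
#' @param label_col Name of the label column (default `"label"`).
#' @param positive Label value treated as the fall class (default
#'   `"fall"`).
#' @return An object of class `fall_lda`: weights `w`, bias `b`, class
#'   means, pooled covariance, priors, the feature order, and the training
#'   scores (for plotting).
#' @export
fall_lda <- function(data, features = feature_columns("full"),
                     label_col = "label", positive = "fall") {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!label_col %in% names(data)) {
    abort(sprintf("label column `%s` not found.", label_col))
  }
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing feature columns: ", toString(missing_cols)))
  }
  y <- data[[label_col]] == positive
  if (!any(y) || all(y)) abort("both classes must be present for training.")
  X <- as.matrix(data[features])
  if (!all(is.finite(X))) abort("features contain non-finite values.")
  n1 <- sum(y); n0 <- sum(!y); p <- ncol(X)
  mu1 <- colMeans(X[y, , drop = FALSE])
  mu0 <- colMeans(X[!y, , drop = FALSE])
  S <- (crossprod(sweep(X[y, , drop = FALSE], 2, mu1)) +
          crossprod(sweep(X[!y, , drop = FALSE], 2, mu0))) / (n1 + n0 - 2)
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv) || rcond(S) < 1e-12) {
    S <- S + diag(1e-6 * sum(diag(S)) / p, p)
    Sinv <- tryCatch(solve(S), error = function(e) {
      abort("pooled covariance is singular even after regularization.")
    })
  }
  priors <- c(other = n0, fall = n1) / (n0 + n1)
  w <- drop(Sinv %*% (mu1 - mu0))
  b <- -sum(w * (mu1 + mu0)) / 2 + log(priors["fall"] / priors["other"])
  model <- structure(
    list(
      w = setNames(w, features), b = unname(b),
      class_means = rbind(other = mu0, fall = mu1),
      pooled_covariance = S, priors = priors, features = features,
      positive = positive, n = c(other = n0, fall = n1)
    ),
    class = "fall_lda"
  )
  model$scores <- tibble::tibble(
    score = discriminant(model, X),
    label = ifelse(y, positive, "other")
  )
  model
}

#' @export
print.fall_lda <- function(x, ...) {
  cat(sprintf(
    "<fall_lda> %d features, trained on %d fall / %d other windows\n",
    length(x$w), x$n["fall"], x$n["other"]
  ))
  invisible(x)
}

#' Linear discriminant score
#'
#' `w' x + b` for one feature vector or a matrix of rows; scores `>= 0` are
#' classified as falls (the boundary itself is inclusive on the fall side).
#'
#' @param model A [fall_lda()] model.
#' @param x Numeric vector of length `p`, a matrix with `p` columns, or a
#'   data frame containing the model's feature columns.
#' @return Numeric score(s).
#' @export
discriminant <- function(model, x) {
  if (!inherits(model, "fall_lda")) abort("`model` must be a fall_lda.")
  if (is.data.frame(x)) x <- as.matrix(x[model$features])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$w)) {
    abort(sprintf("feature dimension mismatch: %d != %d.",
                  ncol(x), length(model$w)))
  }
  drop(x %*% model$w + model$b)
}

#' @describeIn fall_lda Predict fall/other labels for new feature rows.
#' @param object A `fall_lda` model.
#' @param newdata Feature data frame.
#' @param ... Unused.
#' @return For `predict()`: a tibble with `score` and `class`.
#' @export
predict.fall_lda <- function(object, newdata, ...) {
  s <- discriminant(object, newdata)
  tibble::tibble(
    score = s,
    class = ifelse(s >= 0, object$positive, "other")
  )
}

#' @describeIn fall_lda Discriminant weights as a tibble (`term`,
#'   `weight`).
#' @param x A `fall_lda` model.
#' @method tidy fall_lda
#' @export
tidy.fall_lda <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = names(x$w), weight = unname(x$w)),
    tibble::tibble(term = "(bias)", weight = x$b)
  )
}

#' @describeIn fall_lda One-row model summary.
#' @method glance fall_lda
#' @export
glance.fall_lda <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$w),
    n_fall = unname(x$n["fall"]),
    n_other = unname(x$n["other"]),
    prior_fall = unname(x$priors["fall"]),
    training_accuracy = mean((x$scores$score >= 0) ==
                               (x$scores$label == x$positive))
  )
}

#' Confusion counts and classification metrics
#'
#' Accuracy, sensitivity (recall of falls), specificity and precision from
#' predicted and true labels. Ratios with a zero denominator are reported
#' as `NA`.
#'
#' @param truth Character/factor vector of true labels.
#' @param pred Character/factor vector of predicted labels, same length.
#' @param positive Label of the positive (fall) class.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`, `precision`.
#' @examples
#' evaluate_predictions(rep(c("fall", "adl"), c(10, 10)),
#'                      rep(c("fall", "adl"), c(9, 11)))
#' @export
evaluate_predictions <- function(truth, pred, positive = "fall") {
  if (length(truth) != length(pred)) {
    abort("`truth` and `pred` must have equal length.")
  }
  if (!length(truth)) abort("`truth` is empty.")
  t_pos <- truth == positive
  p_pos <- pred == positive
  tp <- sum(t_pos & p_pos); fp <- sum(!t_pos & p_pos)
  tn <- sum(!t_pos & !p_pos); fn <- sum(t_pos & !p_pos)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / length(truth),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    precision = ratio(tp, tp + fp)
  )
}

#' Stratified k-fold cross-validation of the LDA classifier
#'
#' Splits windows into `folds` stratified folds (seeded), trains
#' [fall_lda()] on each training portion and scores the held-out fold.
#'
#' @inheritParams fall_lda
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return A tibble with one row per fold: `fold`, `n_test` and the
#'   [evaluate_predictions()] metrics.
#' @export
crossval_lda <- function(data, features = feature_columns("full"),
                         folds = 5L, seed = 1L, label_col = "label",
                         positive = "fall") {
  if (!label_col %in% names(data)) {
    abort(sprintf("label column `%s` not found.", label_col))
  }
  set.seed(as.integer(seed))
  y <- data[[label_col]]
  fold_id <- integer(nrow(data))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  purrr::map_dfr(seq_len(folds), function(k) {
    train <- data[fold_id != k, ]
    test <- data[fold_id == k, ]
    model <- fall_lda(train, features = features, label_col = label_col,
                      positive = positive)
    pred <- predict(model, test)
    truth <- ifelse(test[[label_col]] == positive, positive, "other")
    dplyr::bind_cols(
      tibble::tibble(fold = k, n_test = nrow(test)),
      evaluate_predictions(truth, pred$class, positive = positive)
    )
  })
}

#' Serialize / restore a trained classifier as JSON
#'
#' Writes all model components (weights, bias, class means, pooled
#' covariance, priors, feature order) to a small versioned JSON document,
#' and reads it back into an equivalent `fall_lda` object.
#'
#' @param model A [fall_lda()] model.
#' @param path File path.
#' @return `write_lda_json()` returns `path` invisibly; `read_lda_json()`
#'   returns a `fall_lda`.
#' @export
write_lda_json <- function(model, path) {
  if (!inherits(model, "fall_lda")) abort("`model` must be a fall_lda.")
  doc <- list(
    format = "fractalfall-lda", version = 1L,
    features = model$features, positive = model$positive,
    w = unname(model$w), b = model$b,
    class_means = list(other = unname(model$class_means["other", ]),
                       fall = unname(model$class_means["fall", ])),
    pooled_covariance = model$pooled_covariance,
    priors = as.list(model$priors), n = as.list(model$n)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lda_json
#' @export
read_lda_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "fractalfall-lda")) {
    abort("not a fractalfall LDA model document.")
  }
  feats <- doc$features
  means <- rbind(other = doc$class_means$other, fall = doc$class_means$fall)
  colnames(means) <- feats
  structure(
    list(
      w = setNames(as.numeric(doc$w), feats), b = as.numeric(doc$b),
      class_means = means,
      pooled_covariance = matrix(unlist(doc$pooled_covariance),
                                 nrow = length(feats)),
      priors = unlist(doc$priors), features = feats,
      positive = doc$positive, n = unlist(doc$n), scores = NULL
    ),
    class = "fall_lda"
  )
}
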