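#' Read a triaxial accelerometer CSV
#'
#' Expects a header with at least `ax`, `ay`, `az` (units g); `time`,
#' `window_id` and `label` columns are kept when present, anything else is
#' dropped. Malformed (non-numeric) cells are rejected with a message
#' naming the offending data line.
#'
#' @param path CSV file path.
#' @return A tibble validated as a triaxial segment.
#' @export
read_accel_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  missing_cols <- setdiff(c("ax", "ay", "az"), names(raw))
  if (length(missing_cols)) {
    abort(paste0("missing required columns: ", toString(missing_cols)))
  }
  for (col in c("ax", "ay", "az", intersect("time", names(raw)))) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      abort(sprintf("non-numeric value in column `%s` at data line %d.",
                    col, if (is.na(bad)) 1L else bad))
    }
    if (anyNA(v)) {
      abort(sprintf("missing value in column `%s` at data line %d.",
                    col, which(is.na(v))[1]))
    }
  }
  keep <- intersect(c("window_id", "label", "time", "t", "ax", "ay", "az"),
                    names(raw))
  as_accel(raw[keep])
}

#' Write a triaxial accelerometer CSV
#'
#' @param accel Data frame with `ax`, `ay`, `az` and optional `time`/`t`,
#'   `window_id`, `label` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(accel, path) {
  accel <- as_accel(accel)
  keep <- intersect(c("window_id", "label", "time", "t", "ax", "ay", "az"),
                    names(accel))
  readr::write_csv(accel[keep], path)
  invisible(path)
}

#' Write / read a feature table CSV
#'
#' The on-disk layout is frozen: `window_id`, `start_index`, optional
#' `label`, then the 14 feature columns in canonical order
#' (`a4_1..a4_8, mu, var, fd1..fd4`), then `sd` and `fd_undefined`.
#'
#' @param features Tibble from [extract_features()].
#' @param path File path.
#' @return `write_features_csv()` returns `path` invisibly;
#'   `read_features_csv()` returns the feature tibble.
#' @export
write_features_csv <- function(features, path) {
  if (!is.data.frame(features)) abort("`features` must be a data frame.")
  cols <- c("window_id", "start_index",
            intersect("label", names(features)),
            feature_columns("full"), "sd", "fd_undefined")
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols)) {
    abort(paste0("missing feature columns: ", toString(missing_cols)))
  }
  readr::write_csv(features[cols], path)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(feature_columns("full"), names(out))
  if (length(missing_cols)) {
    abort(paste0("missing feature columns: ", toString(missing_cols)))
  }
  out
}

#' Reference per-activity fractional-integration orders
#'
#' A small bundled table of mean fractional-integration orders `d_tilde`
#' (and, for falls, the stationary-series order `d`) reported for fall and
#' activity classes of a public pelvis-worn accelerometer fall dataset.
#' Feeding these through [nonstationary_fractal_params()] reproduces the
#' per-activity Hurst exponents and fractal dimensions that motivate the
#' fractal feature set: falls sit near `fd = 1.01` while every activity of
#' daily life is at 1.5 or above.
#'
#' @return A tibble with columns `activity`, `d_tilde` and `d` (the
#'   stationary-series order where reported, otherwise `NA`).
#' @examples
#' ref <- activity_fractal_reference()
#' nonstationary_fractal_params(d_tilde = ref$d_tilde)
#' @export
activity_fractal_reference <- function() {
  path <- system.file("extdata", "activity_fractal_reference.csv",
                      package = "fractalfall", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    activity = readr::col_character(),
                    d_tilde = readr::col_double(),
                    d = readr::col_double()
                  ))
}
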