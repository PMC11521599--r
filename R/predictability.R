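#' Lagged (autoregressive) design matrix
#'
#' Row `i` holds `(x[i], ..., x[i + n_lags - 1])` and the target is
#' `x[i + n_lags]`: a one-step-ahead autoregressive framing.
#'
#' @param x numeric vector.
#' @param n_lags number of lags (>= 1, < length(x)).
#' @return list with `X` (`(N - n_lags) x n_lags` matrix) and `y`
#'   (length `N - n_lags`).
#' @export
build_lagged_design <- function(x, n_lags) {
  if (!is.numeric(n_lags) || n_lags < 1) stop("n_lags must be >= 1")
  n <- length(x)
  if (n <= n_lags) stop("series too short for n_lags = ", n_lags)
  rows <- n - n_lags
  X <- matrix(0, rows, n_lags)
  for (j in seq_len(n_lags)) X[, j] <- x[j:(j + rows - 1)]
  list(X = X, y = x[(n_lags + 1):n])
}

#' Pearson product-moment correlation
#'
#' @param a,b equal-length numeric vectors (length >= 2) with non-zero
#'   variance.
#' @return `r` in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("need two equal-length vectors of length >= 2")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(a, b, method = "pearson")
}

#' Random-forest predictability of one channel
#'
#' Trains a random-forest regressor on the lagged autoregressive design of
#' the first `train_fraction` (contiguous) of the series and predicts the
#' remaining samples one step ahead from their true lags; the score is the
#' Pearson correlation between predicted and actual test values (the
#' quantity the source field often reports under the label "R2" despite
#' ranging over [-1, 1]). A constant test segment (or constant predictions)
#' makes the correlation undefined: the result is flagged and `r` is `NaN`.
#'
#' @param x numeric vector, a channel already prepared by
#'   [predict_preprocess()] (250 Hz).
#' @param config an [analysis_config()] (`n_lags`, `n_trees`,
#'   `train_fraction`, `seed`).
#' @param channel_id optional label carried into the result.
#' @return list of class `prediction_result`: `channel`, `r`, `flagged`,
#'   `split_index` (last training row, `floor(train_fraction * N)` in
#'   sample units), `predicted`, `actual`.
#' @export
fit_predict_rf <- function(x, config = analysis_config(), channel_id = NA) {
  stopifnot(is.numeric(x))
  des <- build_lagged_design(x, config$n_lags)
  n <- length(x)
  split <- floor(config$train_fraction * n)
  if (split <= config$n_lags || split >= n)
    stop("training split leaves no usable rows")
  # design row i targets x[i + n_lags]; train on targets up to the split
  train_rows <- seq_len(split - config$n_lags)
  test_rows <- setdiff(seq_len(nrow(des$X)), train_rows)
  df_train <- data.frame(des$X[train_rows, , drop = FALSE],
                         .target = des$y[train_rows])
  fit <- ranger::ranger(
    dependent.variable.name = ".target", data = df_train,
    num.trees = config$n_trees, num.threads = 1,
    seed = stage_seed(config$seed, "rf", 1L))
  pred <- stats::predict(fit,
                         data = data.frame(des$X[test_rows, , drop = FALSE]),
                         num.threads = 1)$predictions
  actual <- des$y[test_rows]
  flagged <- stats::sd(actual) == 0 || stats::sd(pred) == 0
  r <- if (flagged) NaN else pearson_r(pred, actual)
  structure(list(channel = channel_id, r = r, flagged = flagged,
                 split_index = split, predicted = pred, actual = actual),
            class = "prediction_result")
}

#' Predictability of every channel of a recording
#'
#' Runs [fit_predict_rf()] on each channel of a
#' [predict_preprocess()]-prepared recording.
#'
#' @param rec a [raw_recording()] at the prediction rate.
#' @param config an [analysis_config()].
#' @return data frame `channel`, `pearson_r`, `flagged`, `split_index`.
#' @export
predictability <- function(rec, config = analysis_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  rows <- lapply(seq_len(nrow(rec$data)), function(ch) {
    res <- tryCatch(
      fit_predict_rf(rec$data[ch, ], config,
                     channel_id = rec$channel_ids[ch]),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(channel = rec$channel_ids[ch], pearson_r = NaN,
                        flagged = TRUE, split_index = NA_integer_))
    data.frame(channel = res$channel, pearson_r = res$r,
               flagged = res$flagged, split_index = res$split_index,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
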