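#' Multi-channel extracellular recording
#'
#' Container for a channels x samples voltage matrix together with its
#' sampling rate, channel labels and the start time of the matrix relative
#' to recording onset. All voltages are in microvolts, all times in seconds,
#' sample indices are 0-based and time windows are half-open `[start, end)`.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param channel_ids character vector of channel labels; defaults to
#'   `"ch01"`, `"ch02"`, ...
#' @param t0 start time of the first sample in seconds relative to
#'   recording onset.
#'
#' @return An object of class `raw_recording` with elements `data`,
#'   `sampling_rate`, `channel_ids`, `t0`.
#' @export
raw_recording <- function(data, sampling_rate, channel_ids = NULL, t0 = 0) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  if (any(!is.finite(data)))
    stop("recording contains non-finite values")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number")
  if (is.null(channel_ids))
    channel_ids <- sprintf("ch%02d", seq_len(nrow(data)))
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nrow(data))
    stop("`channel_ids` length must equal the number of channels")
  structure(
    list(data = data, sampling_rate = as.numeric(sampling_rate),
         channel_ids = channel_ids, t0 = as.numeric(t0)),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.3f s, t0 = %g s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              rec_duration(x), x$t0))
  invisible(x)
}

#' Duration of a recording in seconds
#'
#' @param rec a [raw_recording()].
#' @return `n_samples / sampling_rate` in seconds.
#' @export
rec_duration <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  ncol(rec$data) / rec$sampling_rate
}

#' Extract a time window from a recording
#'
#' Returns the half-open window `[start, end)`, expressed in seconds
#' relative to recording onset (i.e. absolute time, taking `t0` into
#' account). The result has exactly `round((end - start) * rate)` samples
#' per channel and an updated `t0`.
#'
#' @param rec a [raw_recording()].
#' @param start,end window bounds in seconds, `0 <= start < end <= t0 + duration`.
#' @return a [raw_recording()] covering the requested window.
#' @export
slice_window <- function(rec, start, end) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!is.finite(start) || !is.finite(end) || start < 0 || start >= end)
    stop("invalid window: need 0 <= start < end")
  rate <- rec$sampling_rate
  rec_end <- rec$t0 + rec_duration(rec)
  if (start < rec$t0 - 1e-9 || end > rec_end + 1e-9)
    stop(sprintf("window [%g, %g) outside recording [%g, %g)",
                 start, end, rec$t0, rec_end))
  i0 <- round((start - rec$t0) * rate)          # 0-based first sample
  n  <- round((end - start) * rate)
  if (i0 + n > ncol(rec$data)) n <- ncol(rec$data) - i0
  raw_recording(rec$data[, (i0 + 1):(i0 + n), drop = FALSE],
                sampling_rate = rate,
                channel_ids = rec$channel_ids,
                t0 = rec$t0 + i0 / rate)
}

#' Read a recording from disk
#'
#' Two on-disk layouts are supported. `"csv"`: samples in rows, one column
#' per channel, header row of channel ids; the sampling rate comes either
#' from the `sampling_rate` argument or from a JSON sidecar
#' (`<path>.json` with fields `sampling_rate_hz`, optionally `channel_ids`
#' and `t0`) as written by [write_recording()]. `"rds"`: a serialized
#' `raw_recording` (bit-exact round trip).
#'
#' @param path file path.
#' @param format `"csv"` or `"rds"`; default guessed from the extension.
#' @param sampling_rate sampling rate in Hz, required for CSV input without
#'   a sidecar.
#' @return a [raw_recording()].
#' @export
read_recording <- function(path, format = c("auto", "csv", "rds"),
                           sampling_rate = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "rds") {
    rec <- readRDS(path)
    if (!inherits(rec, "raw_recording")) stop("RDS file is not a raw_recording")
    if (any(!is.finite(rec$data))) stop("recording contains non-finite values")
    return(rec)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 1 || nrow(df) < 1) stop("empty CSV recording")
  sidecar <- paste0(path, ".json")
  t0 <- 0
  ids <- colnames(df)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(sampling_rate)) sampling_rate <- meta$sampling_rate_hz
    if (!is.null(meta$t0)) t0 <- meta$t0
    if (!is.null(meta$channel_ids)) ids <- meta$channel_ids
  }
  if (is.null(sampling_rate))
    stop("sampling rate missing: pass `sampling_rate` or provide a JSON sidecar")
  m <- t(as.matrix(df))              # stored samples x channels
  if (!is.numeric(m)) stop("non-numeric values in CSV recording")
  dimnames(m) <- NULL
  raw_recording(m, sampling_rate = sampling_rate, channel_ids = ids, t0 = t0)
}

#' Write a recording to disk
#'
#' CSV output stores samples in rows (one column per channel, header of
#' channel ids) at 15 significant digits plus a JSON metadata sidecar
#' `<path>.json`; RDS output is bit-exact.
#'
#' @param rec a [raw_recording()].
#' @param path destination path.
#' @param format `"csv"` or `"rds"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "rds")) {
  stopifnot(inherits(rec, "raw_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv"
  if (format == "rds") {
    saveRDS(rec, path)
    return(invisible(path))
  }
  df <- as.data.frame(t(rec$data))
  colnames(df) <- rec$channel_ids
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(sampling_rate_hz = rec$sampling_rate,
         channel_ids = rec$channel_ids, t0 = rec$t0),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write result tables and a run manifest
#'
#' Writes one CSV per table plus `manifest.json` echoing the configuration,
#' seed and package version.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if needed).
#' @param config an [analysis_config()] or any list to echo into the manifest.
#' @param seed the seed used for the run (echoed into the manifest).
#' @param overwrite overwrite existing files? Default `FALSE`.
#' @return invisibly, the manifest as a list.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL,
                          overwrite = FALSE) {
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("`tables` must be a fully named list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    if (file.exists(f) && !overwrite)
      stop("output exists (use overwrite = TRUE): ", f)
    utils::write.csv(as.data.frame(tables[[nm]]), f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    tables = basename(files),
    seed = seed,
    config = config,
    package_version = as.character(utils::packageVersion("astromea")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mf <- file.path(out_dir, "manifest.json")
  if (file.exists(mf) && !overwrite)
    stop("output exists (use overwrite = TRUE): ", mf)
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
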