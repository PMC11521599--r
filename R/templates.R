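#' Parametric spike-waveform templates
#'
#' Builds a noise-free extracellular spike template as a sum of
#' Gaussian-windowed phases, on the same 3 ms window layout used for spike
#' cutouts (1 ms before the main peak, 2 ms after). Five shape classes are
#' provided: regular spiking (RS, broad negative trough with a slow positive
#' afterwave), fast spiking (FS, narrow trough with an early afterwave),
#' triphasic spiking (TS, prominent positive-negative-positive sequence),
#' compound spiking (CS, two distinct negative troughs) and positive
#' spiking (PS, dominant positive peak). The template is scaled so its
#' extreme value equals `peak_amplitude` (negative for RS/FS/TS/CS,
#' positive for PS).
#'
#' @param class one of `"RS"`, `"FS"`, `"TS"`, `"CS"`, `"PS"`.
#' @param peak_amplitude signed peak voltage in microvolts; must be negative
#'   for RS/FS/TS/CS and positive for PS.
#' @param duration_params optional list with numeric vectors `amp`
#'   (relative phase amplitudes, the main phase being +/-1), `center_ms`
#'   (phase centers relative to the main peak) and `width_ms` (Gaussian
#'   sigma of each phase); defaults depend on `class`.
#' @param sampling_rate sampling rate in Hz.
#' @return numeric vector of `round(0.001 * rate) + round(0.002 * rate) + 1`
#'   voltage samples, main extremum at index `round(0.001 * rate) + 1`.
#' @export
make_waveform_template <- function(class, peak_amplitude,
                                   duration_params = NULL,
                                   sampling_rate = 25000) {
  phases <- switch(class,
    RS = list(amp = c(0.10, -1.00, 0.25),
              center_ms = c(-0.50, 0.00, 1.00),
              width_ms  = c(0.15, 0.20, 0.30)),
    FS = list(amp = c(0.08, -1.00, 0.30),
              center_ms = c(-0.30, 0.00, 0.30),
              width_ms  = c(0.10, 0.09, 0.12)),
    TS = list(amp = c(0.30, -1.00, 0.35),
              center_ms = c(-0.50, 0.00, 0.80),
              width_ms  = c(0.18, 0.20, 0.25)),
    CS = list(amp = c(0.08, -1.00, -0.50, 0.15),
              center_ms = c(-0.50, 0.00, 0.60, 1.40),
              width_ms  = c(0.12, 0.15, 0.15, 0.20)),
    PS = list(amp = c(1.00, -0.20),
              center_ms = c(0.00, 0.70),
              width_ms  = c(0.25, 0.30)),
    stop("unknown waveform class: ", class)
  )
  if (!is.null(duration_params)) {
    for (nm in names(duration_params)) phases[[nm]] <- duration_params[[nm]]
    if (length(unique(lengths(phases))) != 1)
      stop("duration_params fields must have equal lengths")
  }
  if (any(abs(phases$center_ms) + 2 * phases$width_ms > 2.0))
    stop("phase widths do not fit inside the 3 ms window")
  negative <- class != "PS"
  if (negative && peak_amplitude >= 0)
    stop(class, " templates require a negative peak_amplitude")
  if (!negative && peak_amplitude <= 0)
    stop("PS templates require a positive peak_amplitude")

  pre  <- round(0.001 * sampling_rate)
  post <- round(0.002 * sampling_rate)
  t_ms <- (-pre:post) / sampling_rate * 1000
  y <- numeric(length(t_ms))
  for (i in seq_along(phases$amp))
    y <- y + phases$amp[i] *
      exp(-0.5 * ((t_ms - phases$center_ms[i]) / phases$width_ms[i])^2)
  # remove the (tiny) Gaussian-tail endpoint offsets so the template starts
  # and ends exactly on baseline zero
  n <- length(y)
  y <- y - (y[1] + (y[n] - y[1]) * (seq_len(n) - 1) / (n - 1))
  extreme <- if (negative) min(y) else max(y)
  y * (peak_amplitude / extreme)
}

#' Layout of a spike cutout / template window
#'
#' @param sampling_rate sampling rate in Hz.
#' @param pre_ms,post_ms window extent around the peak, ms.
#' @return list with `pre`, `post` (samples) and `length`.
#' @export
cutout_layout <- function(sampling_rate, pre_ms = 1, post_ms = 2) {
  pre <- round(pre_ms / 1000 * sampling_rate)
  post <- round(post_ms / 1000 * sampling_rate)
  list(pre = pre, post = post, length = pre + post + 1L)
}
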