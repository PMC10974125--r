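#' Preprocessing configuration
#'
#' Parameters of the six-stage conditioning pipeline applied to extracted
#' MMG and raw sEMG channels: bandpass edges (Hz), Butterworth order
#' (applied forward-backward, so zero phase), linear-envelope low-pass
#' cutoff, and the normalization scheme.
#'
#' @param band_low_hz lower bandpass edge, default 10 Hz.
#' @param band_high_hz upper bandpass edge, default 450 Hz.
#' @param filter_order even Butterworth order, default 4.
#' @param envelope_cutoff_hz linear-envelope low-pass cutoff, default 5 Hz
#'   (must stay below `band_low_hz`).
#' @param normalization `"minmax_01"` (per channel per trial, range exactly
#'   `[0, 1]`) or `"zscore"`.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(band_low_hz = 10, band_high_hz = 450,
                              filter_order = 4L, envelope_cutoff_hz = 5,
                              normalization = c("minmax_01", "zscore")) {
  normalization <- match.arg(normalization)
  if (band_low_hz <= 0 || band_high_hz <= band_low_hz) {
    stop("need 0 < band_low_hz < band_high_hz", call. = FALSE)
  }
  if (filter_order %% 2 != 0) stop("filter_order must be even", call. = FALSE)
  if (envelope_cutoff_hz >= band_low_hz) {
    stop("envelope_cutoff_hz must be below band_low_hz", call. = FALSE)
  }
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 filter_order = as.integer(filter_order),
                 envelope_cutoff_hz = envelope_cutoff_hz,
                 normalization = normalization),
            class = "preprocess_config")
}

#' DC offset elimination
#'
#' @param signal numeric vector.
#' @return the signal minus its mean (idempotent).
#' @export
remove_dc <- function(signal) {
  signal <- as.numeric(signal)
  if (!all(is.finite(signal))) stop("DC-removal stage: signal contains NaN/Inf", call. = FALSE)
  signal - mean(signal)
}

#' Zero-phase Butterworth bandpass
#'
#' Butterworth bandpass of the configured order applied forward-backward
#' (`signal::filtfilt`), giving flat passband gain (within 1 dB) and no
#' phase lag.
#'
#' @param signal numeric vector.
#' @param rate_hz sampling rate; `band_high_hz` must stay below Nyquist.
#' @param config a [preprocess_config()].
#' @return filtered signal, same length.
#' @export
bandpass <- function(signal, rate_hz, config = preprocess_config()) {
  if (config$band_high_hz >= rate_hz / 2) {
    stop("bandpass stage: band edge at or above Nyquist", call. = FALSE)
  }
  bf <- signal::butter(config$filter_order / 2,
                       c(config$band_low_hz, config$band_high_hz) / (rate_hz / 2),
                       type = "pass")
  as.numeric(signal::filtfilt(bf, as.numeric(signal)))
}

#' Full-wave rectification
#'
#' @param signal numeric vector.
#' @return elementwise absolute value.
#' @export
full_wave_rectify <- function(signal) abs(as.numeric(signal))

#' Linear envelope
#'
#' Zero-phase Butterworth low-pass (order 4 by default) of the rectified
#' signal — the standard amplitude proxy for muscle activation. Negative
#' numerical undershoot is clipped to 0.
#'
#' @param signal nonnegative (rectified) numeric vector.
#' @param rate_hz sampling rate.
#' @param config a [preprocess_config()]; uses `envelope_cutoff_hz`.
#' @return nonnegative envelope, same length.
#' @export
linear_envelope <- function(signal, rate_hz, config = preprocess_config()) {
  bf <- signal::butter(4, config$envelope_cutoff_hz / (rate_hz / 2), type = "low")
  out <- as.numeric(signal::filtfilt(bf, as.numeric(signal)))
  pmax(out, 0)
}

#' Amplitude normalization
#'
#' `minmax_01` rescales to range exactly `[0, 1]`; `zscore` to mean 0, sd 1.
#' A constant signal yields all zeros with a warning under `minmax_01` and
#' an error under `zscore`.
#'
#' @param signal numeric vector.
#' @param mode `"minmax_01"` or `"zscore"`.
#' @return normalized signal.
#' @export
normalize_signal <- function(signal, mode = c("minmax_01", "zscore")) {
  mode <- match.arg(mode)
  signal <- as.numeric(signal)
  rng <- range(signal)
  if (mode == "minmax_01") {
    if (rng[1] == rng[2]) {
      warning("constant signal: min-max normalization returns all zeros")
      return(rep(0, length(signal)))
    }
    (signal - rng[1]) / (rng[2] - rng[1])
  } else {
    s <- sd(signal)
    if (s == 0) stop("z-score normalization undefined for a constant signal", call. = FALSE)
    (signal - mean(signal)) / s
  }
}

#' Six-stage conditioning of one channel
#'
#' Applies stages 2-6 of the pipeline in order: DC removal, 10-450 Hz
#' zero-phase bandpass, full-wave rectification, linear envelope, and
#' normalization. Stage 1 (DE-VMD extraction) is [extract_mmg()]; for
#' `kind = "mmg"` the input is its `mmg` output, for `kind = "semg"` the raw
#' electrode trace. The wide bandpass is applied to both signal kinds; the
#' MMG entering this stage is already band-limited by extraction, so the
#' wider filter is harmless there. Output length equals input length at
#' every stage (no decimation).
#'
#' @param signal numeric vector.
#' @param rate_hz sampling rate.
#' @param config a [preprocess_config()].
#' @param kind `"mmg"` or `"semg"` (recorded for provenance; the stages are
#'   identical).
#' @return conditioned envelope, in `[0, 1]` under min-max normalization.
#' @export
preprocess_channel <- function(signal, rate_hz, config = preprocess_config(),
                               kind = c("mmg", "semg")) {
  kind <- match.arg(kind)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("preprocess stage '%s' (%s): %s", name, kind,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  x <- stage("remove_dc", remove_dc(signal))
  x <- stage("bandpass", bandpass(x, rate_hz, config))
  x <- stage("rectify", full_wave_rectify(x))
  x <- stage("linear_envelope", linear_envelope(x, rate_hz, config))
  stage("normalize", normalize_signal(x, config$normalization))
}

#' Condition a whole multi-channel trace
#'
#' Runs [preprocess_channel()] on every channel of a trace.
#'
#' @param trace a [signal_trace()].
#' @param config a [preprocess_config()].
#' @param kind `"mmg"` or `"semg"`.
#' @return a [signal_trace()] of conditioned envelopes (unit: normalized).
#' @export
preprocess_trace <- function(trace, config = preprocess_config(),
                             kind = c("mmg", "semg")) {
  kind <- match.arg(kind)
  out <- t(apply(trace$samples, 1, preprocess_channel,
                 rate_hz = trace$rate_hz, config = config, kind = kind))
  signal_trace(out, trace$rate_hz, trace$channel_names, "normalized")
}
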