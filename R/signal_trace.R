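#' Multi-channel uniformly sampled signal trace
#'
#' `signal_trace()` is the universal currency of the pipeline: a channel-major
#' real matrix (`n_channels x n_samples`) plus the sampling rate, channel
#' names and per-channel units. All channels share one length and one rate.
#'
#' @param samples numeric matrix (`n_channels x n_samples`) or a numeric
#'   vector (treated as one channel).
#' @param rate_hz positive sampling rate in samples/second.
#' @param channel_names character vector of unique channel names; defaults to
#'   `ch1, ch2, ...`.
#' @param units character vector of per-channel units, recycled if length 1.
#'
#' @return An object of class `signal_trace`.
#' @examples
#' tr <- signal_trace(rbind(sin(1:100 / 10), cos(1:100 / 10)), rate_hz = 100,
#'                    channel_names = c("x", "y"), units = "m/s^2")
#' n_samples(tr)
#' @export
signal_trace <- function(samples, rate_hz, channel_names = NULL, units = "a.u.") {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = 1)
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (channels x samples) or numeric vector",
         call. = FALSE)
  }
  storage.mode(samples) <- "double"
  if (nrow(samples) < 1L) stop("a signal_trace needs at least one channel", call. = FALSE)
  if (ncol(samples) < 1L) stop("a signal_trace needs at least one sample", call. = FALSE)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) || rate_hz <= 0) {
    stop("`rate_hz` must be a single positive number", call. = FALSE)
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(samples)))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(samples)) {
    stop("`channel_names` must have one entry per channel", call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("channel names must be unique", call. = FALSE)
  }
  units <- as.character(units)
  if (length(units) == 1L) units <- rep(units, nrow(samples))
  if (length(units) != nrow(samples)) {
    stop("`units` must be length 1 or one per channel", call. = FALSE)
  }
  rownames(samples) <- channel_names
  structure(
    list(samples = samples, rate_hz = as.numeric(rate_hz),
         channel_names = channel_names, units = units),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              n_channels(x), n_samples(x), x$rate_hz, duration_s(x)))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Trace dimensions and duration
#'
#' @param trace a [signal_trace()].
#' @return `n_channels()`/`n_samples()` return integers; `duration_s()` the
#'   record length in seconds.
#' @export
n_channels <- function(trace) nrow(trace$samples)

#' @rdname n_channels
#' @export
n_samples <- function(trace) ncol(trace$samples)

#' @rdname n_channels
#' @export
duration_s <- function(trace) ncol(trace$samples) / trace$rate_hz

#' Extract one channel of a trace as a numeric vector
#'
#' @param trace a [signal_trace()].
#' @param channel channel name or index.
#' @return numeric vector of samples.
#' @export
trace_channel <- function(trace, channel) {
  stopifnot(inherits(trace, "signal_trace"))
  if (is.character(channel)) {
    idx <- match(channel, trace$channel_names)
    if (is.na(idx)) stop("unknown channel: ", channel, call. = FALSE)
  } else {
    idx <- as.integer(channel)
    if (idx < 1L || idx > n_channels(trace)) stop("channel index out of range", call. = FALSE)
  }
  as.numeric(trace$samples[idx, ])
}

#' Keep a subset of channels
#'
#' @param trace a [signal_trace()].
#' @param channels channel names or indices.
#' @return a [signal_trace()] with the selected channels, order preserved.
#' @export
trace_select <- function(trace, channels) {
  stopifnot(inherits(trace, "signal_trace"))
  if (is.character(channels)) {
    idx <- match(channels, trace$channel_names)
    if (anyNA(idx)) stop("unknown channel(s): ",
                         paste(channels[is.na(idx)], collapse = ", "), call. = FALSE)
  } else idx <- as.integer(channels)
  signal_trace(trace$samples[idx, , drop = FALSE], trace$rate_hz,
               trace$channel_names[idx], trace$units[idx])
}

#' @export
as_tibble.signal_trace <- function(x, ...) {
  n <- n_samples(x)
  tibble::tibble(
    time_s = rep((seq_len(n) - 1) / x$rate_hz, times = n_channels(x)),
    channel = rep(x$channel_names, each = n),
    value = as.numeric(t(x$samples))
  )
}

#' Plot a signal trace
#'
#' One facet per channel, time on the x axis.
#'
#' @param object a [signal_trace()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.signal_trace <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' A multimodal recording: raw acceleration, sEMG and joint-acceleration targets
#'
#' Bundles the three synchronized traces of one trial. All traces must share
#' the sampling rate and duration.
#'
#' @param raw_accel [signal_trace()] of raw accelerometer axes (m/s^2).
#' @param semg [signal_trace()] of surface-EMG channels (mV).
#' @param targets [signal_trace()] of joint rotational accelerations (rad/s^2).
#' @param meta named list of free-form metadata (exercise, trial id, seed...).
#' @return an object of class `recording`.
#' @export
recording <- function(raw_accel, semg, targets, meta = list()) {
  for (tr in list(raw_accel, semg, targets)) {
    if (!inherits(tr, "signal_trace")) stop("all components must be signal_trace", call. = FALSE)
  }
  rates <- c(raw_accel$rate_hz, semg$rate_hz, targets$rate_hz)
  if (length(unique(rates)) != 1L) {
    stop("raw_accel, semg and targets must share one sampling rate", call. = FALSE)
  }
  ns <- c(n_samples(raw_accel), n_samples(semg), n_samples(targets))
  if (length(unique(ns)) != 1L) {
    stop("raw_accel, semg and targets must cover the same duration", call. = FALSE)
  }
  structure(list(raw_accel = raw_accel, semg = semg, targets = targets,
                 meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %g Hz, %.1f s | accel %d ch, sEMG %d ch, targets %d ch\n",
              x$raw_accel$rate_hz, duration_s(x$raw_accel),
              n_channels(x$raw_accel), n_channels(x$semg), n_channels(x$targets)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
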