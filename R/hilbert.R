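#' Analytic signal and Hilbert envelope
#'
#' `analytic_signal()` returns the complex analytic signal via the FFT
#' half-spectrum construction; `hilbert_envelope()` its elementwise
#' magnitude, the instantaneous amplitude.
#'
#' @param signal finite numeric vector.
#' @return `analytic_signal()`: complex vector; `hilbert_envelope()`:
#'   nonnegative numeric vector of the same length.
#' @examples
#' env <- hilbert_envelope(sin(2 * pi * 20 * seq(0, 2, by = 1e-3)))
#' mean(env[200:1800])  # ~1 for a unit tone away from edges
#' @export
analytic_signal <- function(signal) {
  signal <- as.numeric(signal)
  if (!all(is.finite(signal))) stop("signal contains NaN/Inf", call. = FALSE)
  n <- length(signal)
  X <- fft(signal)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' @rdname analytic_signal
#' @export
hilbert_envelope <- function(signal) {
  Mod(analytic_signal(signal))
}

#' Marginal Hilbert Spectrum
#'
#' Per IMF, the instantaneous amplitude (Hilbert envelope) and instantaneous
#' frequency (central difference of the unwrapped analytic phase, clipped to
#' `[0, rate/2]`) are computed per sample; squared amplitude is then
#' accumulated into frequency bins over time, giving the total energy
#' contribution of each frequency.
#'
#' @param imfs numeric matrix (`K x n_samples`) or a single numeric vector.
#' @param rate_hz sampling rate.
#' @param n_freq_bins number of equal-width bins spanning `[0, rate/2]`.
#' @return a `marginal_spectrum`: list with `freqs_hz` (bin centers, strictly
#'   increasing) and `energy` (nonnegative, same length).
#' @export
marginal_hilbert_spectrum <- function(imfs, rate_hz, n_freq_bins = 256L) {
  if (is.vector(imfs)) imfs <- matrix(imfs, nrow = 1)
  if (nrow(imfs) < 1L) stop("need at least one IMF", call. = FALSE)
  if (ncol(imfs) < 2L) stop("IMFs must have >= 2 samples to define a phase derivative",
                            call. = FALSE)
  n_freq_bins <- as.integer(n_freq_bins)
  nyq <- rate_hz / 2
  edges <- seq(0, nyq, length.out = n_freq_bins + 1L)
  energy <- numeric(n_freq_bins)
  for (k in seq_len(nrow(imfs))) {
    z <- analytic_signal(imfs[k, ])
    amp <- Mod(z)
    if (all(amp == 0)) next
    phase <- unwrap_phase(Arg(z))
    inst_f <- central_diff(phase) * rate_hz / (2 * pi)
    inst_f <- pmin(pmax(inst_f, 0), nyq)
    bin <- pmin(pmax(findInterval(inst_f, edges, rightmost.closed = TRUE), 1L),
                n_freq_bins)
    acc <- tapply(amp^2, bin, sum)
    energy[as.integer(names(acc))] <- energy[as.integer(names(acc))] + acc
  }
  structure(list(freqs_hz = (edges[-1] + edges[-length(edges)]) / 2,
                 energy = energy),
            class = "marginal_spectrum")
}

#' Energy centroid of a marginal spectrum
#'
#' @param ms a `marginal_spectrum`.
#' @return the energy-weighted mean frequency in Hz, or `NA` for zero energy.
#' @export
spectrum_centroid <- function(ms) {
  stopifnot(inherits(ms, "marginal_spectrum"))
  tot <- sum(ms$energy)
  if (tot <= 0) return(NA_real_)
  sum(ms$freqs_hz * ms$energy) / tot
}

#' @export
print.marginal_spectrum <- function(x, ...) {
  cat(sprintf("<marginal_spectrum> %d bins over [%.1f, %.1f] Hz, centroid %.2f Hz\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              spectrum_centroid(x)))
  invisible(x)
}

#' @export
as_tibble.marginal_spectrum <- function(x, ...) {
  tibble::tibble(freq_hz = x$freqs_hz, energy = x$energy)
}

#' Plot a marginal Hilbert spectrum
#'
#' @param object a `marginal_spectrum`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.marginal_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$freq_hz, y = .data$energy)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "frequency (Hz)", y = "energy")
}

unwrap_phase <- function(phi) {
  d <- diff(phi)
  jumps <- round(d / (2 * pi))
  phi - c(0, cumsum(jumps)) * 2 * pi
}

central_diff <- function(x) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d
}
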