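#' Synthetic recording configuration
#'
#' Defines the statistical structure the extraction and estimation methods
#' assume: self-paced low-frequency limb oscillation (the pseudo-acceleration
#' source), 10-50 Hz muscle vibration (MMG) and 20-450 Hz electrical
#' activity (sEMG), both amplitude-modulated by muscle activation that is a
#' rectified, smoothed, delayed mixing of the joint accelerations, plus
#' wideband sensor noise at a set SNR.
#'
#' @param exercise `"bicep_curl"`, `"lateral_raise"` or `"frontal_raise"`
#'   (selects the muscle-to-axis mixing weights).
#' @param duration_s record length in seconds (>= 2).
#' @param rate_hz sampling rate, default 1000.
#' @param motion_freq_hz interval of self-paced oscillation frequencies.
#' @param mmg_band_hz MMG carrier band.
#' @param semg_band_hz sEMG carrier band.
#' @param pseudo_accel_cutoff_hz documentation of the pseudo-acceleration
#'   band edge; the kinematic acceleration is band-limited well below it by
#'   construction.
#' @param snr_db accelerometer signal-to-noise ratio (signal =
#'   pseudo-acceleration + MMG) in dB.
#' @param activation_delay_ms electromechanical-style lag between joint
#'   acceleration and the activation that modulates the carriers.
#' @param n_sensors number of muscle sensors (each: 3 accelerometer axes +
#'   1 sEMG channel).
#' @param seed RNG seed; the whole recording is a deterministic function of
#'   the config.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(exercise = c("bicep_curl", "lateral_raise",
                                          "frontal_raise"),
                             duration_s = 60, rate_hz = 1000,
                             motion_freq_hz = c(0.3, 0.7),
                             mmg_band_hz = c(10, 50),
                             semg_band_hz = c(20, 450),
                             pseudo_accel_cutoff_hz = 5,
                             snr_db = 15, activation_delay_ms = 50,
                             n_sensors = 4L, seed = 1L) {
  exercise <- match.arg(exercise)
  if (duration_s < 2) stop("duration_s must be >= 2", call. = FALSE)
  nyq <- rate_hz / 2
  if (mmg_band_hz[2] >= nyq || semg_band_hz[2] >= nyq) {
    stop("carrier bands must lie below Nyquist", call. = FALSE)
  }
  structure(list(exercise = exercise, duration_s = duration_s,
                 rate_hz = rate_hz, motion_freq_hz = motion_freq_hz,
                 mmg_band_hz = mmg_band_hz, semg_band_hz = semg_band_hz,
                 pseudo_accel_cutoff_hz = pseudo_accel_cutoff_hz,
                 snr_db = snr_db, activation_delay_ms = activation_delay_ms,
                 n_sensors = as.integer(n_sensors), seed = as.integer(seed)),
            class = "synthetic_config")
}

# brickwall FFT bandpass: exact band limitation, no filter transients
fft_bandpass <- function(x, rate_hz, lo, hi) {
  n <- length(x)
  X <- fft(x)
  f <- (seq_len(n) - 1) * rate_hz / n
  f <- pmin(f, rate_hz - f)  # two-sided
  X[f < lo | f > hi] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

# zero-phase Gaussian smoother (sd in samples)
gauss_smooth <- function(x, sd_samples) {
  half <- ceiling(4 * sd_samples)
  k <- exp(-0.5 * ((-half):half / sd_samples)^2)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
}

# smooth narrowband oscillation: a sum of random-phase sinusoids with
# frequencies drawn in the band (band-limited by construction, so no
# low-frequency IIR filtering is needed)
narrowband_oscillation <- function(n, rate_hz, band, n_tones = 8L) {
  t <- (seq_len(n) - 1) / rate_hz
  freqs <- runif(n_tones, band[1], band[2])
  phases <- runif(n_tones, 0, 2 * pi)
  amps <- runif(n_tones, 0.3, 1)
  x <- colSums(amps * sin(outer(2 * pi * freqs, t) + phases))
  x / sd(x)
}

exercise_mixing <- function(exercise) {
  switch(exercise,
    bicep_curl = list(
      A = rbind(c(1, 0), c(0.5, 0.6), c(0.3, -0.5)),
      W = rbind(c(1, 0.2, 0), c(-1, 0.2, 0),
                c(0.3, 1, -0.4), c(-0.3, -1, 0.4))),
    lateral_raise = list(
      A = rbind(c(0.9, 0.2), c(0.2, 0.8), c(0.5, 0.3)),
      W = rbind(c(0.9, 0.3, 0.2), c(-0.9, 0.3, -0.2),
                c(0.2, 0.9, 0.5), c(-0.2, -0.9, -0.5))),
    frontal_raise = list(
      A = rbind(c(1, -0.3), c(0.4, 0.5), c(-0.3, 0.6)),
      W = rbind(c(1, -0.2, 0.3), c(-1, 0.2, 0.3),
                c(0.4, 0.8, -0.6), c(-0.4, -0.8, 0.6)))
  )
}

#' Simulate joint motion and muscle activation
#'
#' Joint angle per axis is a mixing of two latent smoothed random-phase
#' oscillations inside `motion_freq_hz`; rotational acceleration is the
#' exact discrete second difference of the angle scaled by `rate_hz^2`
#' (rad/s^2). Activation per muscle is a rectified, Gaussian-smoothed,
#' delayed, saturating linear combination of the joint accelerations with
#' exercise-specific mixing weights; it lies in `[0, 1]`.
#'
#' Uses the current RNG state; [assemble_recording()] seeds it from the
#' config.
#'
#' @param config a [synthetic_config()].
#' @return list with `angle` (3 x n), `joint_accel` (3 x n, rad/s^2) and
#'   `activation` (n_sensors x n, in `[0, 1]`).
#' @export
simulate_motion <- function(config) {
  n <- round(config$duration_s * config$rate_hz)
  rate <- config$rate_hz
  mix <- exercise_mixing(config$exercise)
  theta <- rbind(
    0.5 * narrowband_oscillation(n, rate, config$motion_freq_hz),
    0.15 * narrowband_oscillation(n, rate, config$motion_freq_hz))
  angle <- mix$A %*% theta
  accel <- matrix(0, 3, n)
  for (a in 1:3) {
    d2 <- diff(angle[a, ], differences = 2) * rate^2
    accel[a, ] <- c(d2[1], d2[1], d2)[1:n]  # pad the first two samples
  }
  delay <- round(config$activation_delay_ms * rate / 1000)
  accel_delayed <- cbind(matrix(accel[, 1], 3, delay), accel)[, 1:n, drop = FALSE]
  drive <- mix$W %*% accel_delayed
  activation <- matrix(0, nrow(drive), n)
  for (m in seq_len(nrow(drive))) {
    u <- pmax(drive[m, ], 0)
    u <- gauss_smooth(u, sd_samples = 0.03 * rate)
    s0 <- 2 * mean(u) + .Machine$double.eps
    activation[m, ] <- pmax(tanh(u / s0), 0)
  }
  list(angle = angle, joint_accel = accel, activation = activation)
}

# constant-envelope FM carrier wandering inside [f_lo, f_hi], plus a small
# band-limited Gaussian component; the near-constant envelope makes the
# Hilbert envelope of the modulated product track the modulator closely
am_carrier <- function(n, rate_hz, band, noise_weight = 0.15) {
  margin <- 0.15 * (band[2] - band[1])
  f_lo <- band[1] + margin; f_hi <- band[2] - margin
  wander <- gauss_smooth(rnorm(n), sd_samples = 0.25 * rate_hz)
  wander <- (wander - min(wander)) / (max(wander) - min(wander) + .Machine$double.eps)
  inst_f <- f_lo + wander * (f_hi - f_lo)
  phase <- 2 * pi * cumsum(inst_f) / rate_hz + runif(1, 0, 2 * pi)
  fm <- cos(phase)
  nb <- fft_bandpass(rnorm(n), rate_hz, band[1], band[2])
  nb <- nb / sd(nb)
  carrier <- fm + noise_weight * nb
  carrier / sd(carrier)
}

#' Synthesize an MMG channel from an activation envelope
#'
#' A 10-50 Hz carrier (constant-envelope frequency-wandering component plus
#' a small band-limited Gaussian component) amplitude-modulated by the
#' activation. At least 90% of the spectral energy falls inside the band,
#' and the Hilbert envelope of the output tracks the activation.
#'
#' @param activation numeric vector in `[0, 1]`.
#' @param config a [synthetic_config()].
#' @param gain peak amplitude scale (m/s^2).
#' @return numeric vector, same length as `activation`.
#' @export
synth_mmg <- function(activation, config, gain = 0.1) {
  n <- length(activation)
  gain * activation * am_carrier(n, config$rate_hz, config$mmg_band_hz)
}

#' Synthesize an sEMG channel from an activation envelope
#'
#' As [synth_mmg()] with the 20-450 Hz band and a millivolt scale.
#'
#' @param activation numeric vector in `[0, 1]`.
#' @param config a [synthetic_config()].
#' @param gain peak amplitude scale (mV).
#' @return numeric vector, same length as `activation`.
#' @export
synth_semg <- function(activation, config, gain = 1) {
  n <- length(activation)
  gain * activation * am_carrier(n, config$rate_hz, config$semg_band_hz)
}

#' Assemble a full synthetic recording with ground truth
#'
#' Simulates motion and activation, synthesizes per-sensor MMG and sEMG,
#' projects the kinematic acceleration and the MMG onto each sensor's three
#' axes, and adds white sensor noise so that each accelerometer channel's
#' signal-to-noise ratio (pseudo-acceleration + MMG vs noise) equals
#' `snr_db`. By construction `raw_accel = pseudo + mmg + noise` exactly,
#' per channel. Fully deterministic given the config (seeded).
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_recording`: `recording` (a [recording()] with
#'   12-channel `raw_accel`, 4-channel `semg`, 3-channel `targets`) and
#'   `ground_truth` (per-channel `pseudo` and `mmg` matrices, per-sensor
#'   `mmg_source` and `activation`, the noise matrix, `angle` and the
#'   per-sensor `primary_axis` channel index).
#' @export
assemble_recording <- function(config = synthetic_config()) {
  set.seed(config$seed)
  n <- round(config$duration_s * config$rate_hz)
  ns <- config$n_sensors
  motion <- simulate_motion(config)

  # fixed sensor geometry: lever arms map joint angular accel (rad/s^2) to
  # linear pseudo-acceleration (m/s^2) per axis; axis 1 is the skin normal
  lever <- matrix(runif(ns * 3 * 3, -0.06, 0.06), ns * 3, 3)
  axis_w <- c(0.9, 0.35, 0.25)  # MMG projection: strongest on the normal

  accel_names <- as.vector(t(outer(paste0("s", seq_len(ns)), c("x", "y", "z"),
                                   paste, sep = "_")))
  pseudo <- lever %*% motion$joint_accel
  mmg_ch <- matrix(0, ns * 3, n)
  mmg_source <- matrix(0, ns, n)
  semg <- matrix(0, ns, n)
  for (s in seq_len(ns)) {
    act <- motion$activation[min(s, nrow(motion$activation)), ]
    mmg_source[s, ] <- synth_mmg(act, config)
    for (a in 1:3) {
      mmg_ch[(s - 1) * 3 + a, ] <- axis_w[a] * mmg_source[s, ]
    }
    semg[s, ] <- synth_semg(act, config)
  }
  clean <- pseudo + mmg_ch
  noise <- matrix(0, ns * 3, n)
  for (ch in seq_len(ns * 3)) {
    p_sig <- mean(clean[ch, ]^2)
    noise[ch, ] <- rnorm(n, sd = sqrt(p_sig / 10^(config$snr_db / 10)))
  }
  raw <- clean + noise

  rec <- recording(
    raw_accel = signal_trace(raw, config$rate_hz, accel_names, "m/s^2"),
    semg = signal_trace(semg, config$rate_hz,
                        paste0("semg", seq_len(ns)), "mV"),
    targets = signal_trace(motion$joint_accel, config$rate_hz,
                           c("joint_x", "joint_y", "joint_z"), "rad/s^2"),
    meta = list(exercise = config$exercise, seed = config$seed))
  structure(list(
    recording = rec,
    ground_truth = list(pseudo = pseudo, mmg = mmg_ch,
                        mmg_source = mmg_source, noise = noise,
                        activation = motion$activation,
                        angle = motion$angle,
                        primary_axis = seq(1, ns * 3, by = 3))
  ), class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat("<synthetic_recording>\n")
  print(x$recording)
  invisible(x)
}

#' Simulate a session of trials across exercises
#'
#' The default fixture: each exercise contributes `n_trials` recordings;
#' trial seeds are derived deterministically from `base_seed`.
#'
#' @param exercises character vector of exercise names.
#' @param n_trials trials per exercise.
#' @param base_seed session seed.
#' @param ... further arguments to [synthetic_config()] (e.g. `duration_s`).
#' @return list of `synthetic_recording` objects with trial metadata.
#' @export
simulate_session <- function(exercises = c("bicep_curl", "lateral_raise",
                                           "frontal_raise"),
                             n_trials = 5L, base_seed = 1L, ...) {
  out <- list()
  k <- 0L
  for (ex in exercises) {
    for (tr in seq_len(n_trials)) {
      k <- k + 1L
      cfg <- synthetic_config(exercise = ex,
                              seed = (base_seed * 1000L + k) %% .Machine$integer.max,
                              ...)
      sr <- assemble_recording(cfg)
      sr$recording$meta$trial <- k
      out[[k]] <- sr
    }
  }
  out
}
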