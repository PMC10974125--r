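# shared fixtures: pure tones and small synthetic recordings, built in code

tone <- function(freq_hz, duration_s = 4, rate_hz = 1000, amp = 1, phase = 0) {
  t <- seq_len(duration_s * rate_hz) / rate_hz
  amp * sin(2 * pi * freq_hz * t + phase)
}

two_tone_fixture <- function() {
  list(x = tone(2) + tone(30), f1 = tone(2), f2 = tone(30), rate = 1000)
}

small_synthetic <- function(seed = 42, duration_s = 10) {
  assemble_recording(synthetic_config(duration_s = duration_s, seed = seed))
}

# small linearly coupled dataset: targets are a fixed linear map of the
# features plus light noise (learnability fixture for the estimators)
linear_fixture <- function(n = 240, seq_len = 10, n_features = 4,
                           n_targets = 2, seed = 7, noise_sd = 0.05) {
  set.seed(seed)
  W <- matrix(rnorm(n_features * n_targets), n_features, n_targets)
  X <- array(rnorm(n * seq_len * n_features), c(n, seq_len, n_features))
  y <- array(0, c(n, seq_len, n_targets))
  for (i in seq_len(n)) {
    y[i, , ] <- X[i, , ] %*% W + noise_sd * rnorm(seq_len * n_targets)
  }
  new_supervised_dataset(
    X = X, y = y, mask = matrix(TRUE, n, seq_len),
    feature_names = paste0("f", seq_len(n_features)),
    target_names = paste0("t", seq_len(n_targets)),
    start_sample = seq_len(n), window_samples = 1L,
    trial_id = rep(1L, n))
}

rel_err <- function(a, b) max(abs(a - b)) / max(abs(b), 1e-12)
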