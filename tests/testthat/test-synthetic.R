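test_that("joint acceleration is the exact second difference of the angle", {
  set.seed(1)
  cfg <- synthetic_config(duration_s = 4, seed = 1)
  m <- simulate_motion(cfg)
  for (a in 1:3) {
    d2 <- diff(m$angle[a, ], differences = 2) * cfg$rate_hz^2
    expect_equal(m$joint_accel[a, -(1:2)], d2, tolerance = 1e-12)
  }
  expect_true(all(m$activation >= 0 & m$activation <= 1))
})

test_that("activation lags the joint acceleration by the configured delay", {
  cfg <- synthetic_config(duration_s = 30, seed = 2, activation_delay_ms = 50)
  set.seed(cfg$seed)
  m <- simulate_motion(cfg)
  mix <- exercise_mixing(cfg$exercise)
  drive <- pmax((mix$W %*% m$joint_accel)[1, ], 0)
  act <- m$activation[1, ]
  lags <- 0:150
  cc <- vapply(lags, function(l) {
    n <- length(act)
    cor(act[(1 + l):n], drive[1:(n - l)])
  }, numeric(1))
  expect_lt(abs(lags[which.max(cc)] - 50), 20)
})

test_that("MMG and sEMG carriers respect their bands and track activation", {
  cfg <- synthetic_config(duration_s = 20, seed = 3)
  set.seed(3)
  act <- 0.2 + 0.6 * (1 + sin(2 * pi * 0.5 * seq_len(20000) / 1000)) / 2
  band_energy <- function(x, rate, band) {
    p <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * rate / length(x)
    f <- pmin(f, rate - f)
    sum(p[f >= band[1] & f <= band[2]]) / sum(p)
  }
  mmg <- synth_mmg(act, cfg)
  expect_gt(band_energy(mmg, 1000, cfg$mmg_band_hz), 0.9)
  env <- hilbert_envelope(mmg)
  expect_gt(cor(env[1000:19000], act[1000:19000]), 0.9)
  expect_equal(synth_mmg(rep(0, 1000), cfg), rep(0, 1000))

  semg <- synth_semg(act, cfg)
  expect_gt(band_energy(semg, 1000, cfg$semg_band_hz), 0.9)
  sm <- gauss_smooth(abs(semg), 100)
  expect_gt(cor(sm[1000:19000], act[1000:19000]), 0.9)
  expect_equal(synth_semg(rep(0, 1000), cfg), rep(0, 1000))
})

test_that("assembled recordings satisfy additivity, SNR and determinism", {
  cfg <- synthetic_config(duration_s = 8, seed = 11, snr_db = 15)
  sr <- assemble_recording(cfg)
  gt <- sr$ground_truth
  raw <- sr$recording$raw_accel$samples
  expect_equal(unname(raw), gt$pseudo + gt$mmg + gt$noise, tolerance = 1e-14)
  for (ch in c(1, 5, 9)) {
    snr <- 10 * log10(mean((gt$pseudo[ch, ] + gt$mmg[ch, ])^2) /
                        mean(gt$noise[ch, ]^2))
    expect_lt(abs(snr - 15), 1)
  }
  sr2 <- assemble_recording(cfg)
  expect_identical(serialize(sr, NULL), serialize(sr2, NULL))
})

test_that("spectral band occupancy holds across seeds (property)", {
  band_energy <- function(x, rate, lo, hi) {
    p <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * rate / length(x)
    f <- pmin(f, rate - f)
    sum(p[f >= lo & f <= hi]) / sum(p)
  }
  for (seed in 1:20) {
    cfg <- synthetic_config(duration_s = 4, seed = seed)
    sr <- assemble_recording(cfg)
    gt <- sr$ground_truth
    s <- gt$primary_axis[1]
    expect_gt(band_energy(gt$mmg[s, ], 1000, 10, 50), 0.9)
    expect_gt(band_energy(gt$pseudo[s, ], 1000, 0, 10), 0.9)
  }
})

test_that("the generated supervised problem is ridge-learnable", {
  # features built from ground-truth activation (no extraction noise):
  # a plain ridge fit from sub-window features to targets must clear 0.5
  sr <- assemble_recording(synthetic_config(duration_s = 40, seed = 6))
  feats <- signal_trace(
    rbind(sr$ground_truth$activation, sr$ground_truth$activation),
    1000, paste0("f", 1:8))
  ds <- build_dataset(feats, sr$recording$targets, windowing_config())
  sp <- split_dataset(ds, 0.25, "by_block", seed = 1)
  Xtr <- apply(sp$train$X, 1, as.numeric)
  Xte <- apply(sp$test$X, 1, as.numeric)
  lambda <- 1e-3
  XtX <- Xtr %*% t(Xtr) + lambda * diag(nrow(Xtr))
  preds <- matrix(0, n_examples(sp$test), length(sp$test$y[1, , ]))
  truth <- matrix(0, n_examples(sp$test), length(sp$test$y[1, , ]))
  ytr <- apply(sp$train$y, 1, as.numeric)
  beta <- solve(XtX, Xtr %*% t(ytr))
  pred <- t(Xte) %*% beta
  r2 <- r2_score(as.numeric(t(apply(sp$test$y, 1, as.numeric))), as.numeric(pred))
  expect_gt(r2, 0.5)
})
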