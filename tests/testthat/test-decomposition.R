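test_that("VMD recovers a single tone's frequency and waveform", {
  x <- tone(30)
  d <- vmd_decompose(x, 1000, vmd_config(K = 1, alpha = 2000))
  expect_lt(abs(d$center_freqs_hz[1] - 30), 0.5)
  expect_gt(cor(d$imfs[1, ], x), 0.99)
  expect_true(d$converged)
  expect_lte(d$n_iters, 500)
})

test_that("VMD separates two tones with accurate center frequencies", {
  fx <- two_tone_fixture()
  d <- vmd_decompose(fx$x, fx$rate, vmd_config(K = 2, alpha = 2000))
  expect_lt(abs(d$center_freqs_hz[1] - 2), 1)
  expect_lt(abs(d$center_freqs_hz[2] - 30), 1)
  expect_gt(cor(d$imfs[1, ], fx$f1), 0.99)
  expect_gt(cor(d$imfs[2, ], fx$f2), 0.99)
  expect_true(all(diff(d$center_freqs_hz) >= 0))
  expect_true(all(d$center_freqs_hz >= 0 & d$center_freqs_hz <= fx$rate / 2))
  expect_true(is.finite(d$rel_recon_error))
})

test_that("VMD handles degenerate and invalid input per contract", {
  d <- vmd_decompose(rep(0, 1024), 1000, vmd_config(K = 3))
  expect_equal(d$imfs, matrix(0, 3, 1024))
  expect_true(d$converged)
  expect_error(vmd_decompose(c(rep(1, 100), NaN), 1000), "NaN")
  expect_error(vmd_decompose(1:4, 1000), "length")
})

test_that("VMD tone recovery is robust across the alpha range", {
  x <- tone(30, duration_s = 2)
  for (alpha in c(200, 2000, 20000)) {
    d <- vmd_decompose(x, 1000, vmd_config(K = 1, alpha = alpha))
    expect_lt(abs(d$center_freqs_hz[1] - 30), 0.5)
  }
})

test_that("decomposing a signal and its mirror extension agree centrally", {
  set.seed(3)
  x <- tone(8, 2) + 0.5 * tone(45, 2) + 0.1 * rnorm(2000)
  n <- length(x)
  ext <- c(rev(x[1:(n / 2)]), x, rev(x[(n / 2 + 1):n]))
  d1 <- vmd_decompose(x, 1000, vmd_config(K = 2, alpha = 2000))
  d2 <- vmd_decompose(ext, 1000, vmd_config(K = 2, alpha = 2000))
  mid1 <- (n / 4 + 1):(3 * n / 4)
  mid2 <- mid1 + n / 2
  for (k in 1:2) {
    rms_diff <- sqrt(mean((d1$imfs[k, mid1] - d2$imfs[k, mid2])^2))
    expect_lt(rms_diff / sqrt(mean(d1$imfs[k, mid1]^2)), 0.02)
  }
})

test_that("EMD separates an oscillation from a trend and reconstructs exactly", {
  x <- tone(30) + seq(0, 1, length.out = 4000)
  d <- emd_decompose(x)
  expect_gt(cor(d$imfs[1, ], tone(30)), 0.95)
  expect_gt(cor(d$residual, seq(0, 1, length.out = 4000)), 0.95)
  recon <- colSums(d$imfs) + d$residual
  expect_lt(rel_err(recon, x), 1e-9)
})

test_that("EMD of a constant/monotone signal yields no IMFs", {
  x <- rep(2.5, 100)
  d <- emd_decompose(x)
  expect_equal(nrow(d$imfs), 0L)
  expect_equal(d$residual, x)
  d2 <- emd_decompose(seq(0, 1, length.out = 100))
  expect_equal(nrow(d2$imfs), 0L)
})

test_that("EMD additivity holds on random signals (property)", {
  for (seed in 1:50) {
    set.seed(seed)
    x <- cumsum(rnorm(256))
    d <- emd_decompose(x, max_imfs = 6)
    recon <- if (nrow(d$imfs)) colSums(d$imfs) + d$residual else d$residual
    expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-9)
  }
})

test_that("Hilbert envelope of a pure tone is ~1 away from edges", {
  env <- hilbert_envelope(tone(20, duration_s = 4))
  interior <- env[400:3600]
  expect_lt(abs(mean(interior) - 1), 0.02)
  expect_true(all(env >= 0))
})

test_that("Hilbert envelope is homogeneous and zero-preserving", {
  x <- tone(15, 1)
  expect_equal(hilbert_envelope(2 * x), 2 * hilbert_envelope(x), tolerance = 1e-12)
  expect_equal(hilbert_envelope(rep(0, 100)), rep(0, 100))
})

test_that("marginal spectrum of a tone concentrates energy at its frequency", {
  ms <- marginal_hilbert_spectrum(tone(30), 1000, n_freq_bins = 250)
  in_band <- ms$freqs_hz >= 28 & ms$freqs_hz <= 32
  expect_gt(sum(ms$energy[in_band]) / sum(ms$energy), 0.9)
  expect_true(all(diff(ms$freqs_hz) > 0))
  expect_true(all(ms$energy >= 0))
})

test_that("marginal spectrum handles zero IMFs and is time-reversal invariant", {
  ms0 <- marginal_hilbert_spectrum(rep(0, 500), 1000)
  expect_true(all(ms0$energy == 0))
  x <- tone(25, 2)
  e1 <- marginal_hilbert_spectrum(x, 1000)$energy
  e2 <- marginal_hilbert_spectrum(rev(x), 1000)$energy
  expect_lt(sum(abs(e1 - e2)) / sum(e1), 0.01)
  expect_error(marginal_hilbert_spectrum(matrix(1, 1, 1), 1000), "2 samples")
})

test_that("rerunning VMD warm-started at a converged solution is a fixed point", {
  fx <- two_tone_fixture()
  d1 <- vmd_decompose(fx$x, fx$rate, vmd_config(K = 2, alpha = 2000))
  d2 <- vmd_decompose(fx$x, fx$rate,
                      vmd_config(K = 2, alpha = 2000, init = "given",
                                 omega_init = d1$center_freqs_hz))
  expect_lte(d2$n_iters, d1$n_iters)
  for (k in 1:2) {
    expect_lt(sqrt(mean((d1$imfs[k, ] - d2$imfs[k, ])^2)) /
                sqrt(mean(d1$imfs[k, ]^2)), 1e-3)
  }
  expect_lt(max(abs(d1$center_freqs_hz - d2$center_freqs_hz)), 0.05)
})
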