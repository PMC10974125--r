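test_that("envelope entropy matches closed forms", {
  expect_equal(envelope_entropy(envelope = rep(1, 100)), 2, tolerance = 1e-12)
  expect_equal(envelope_entropy(envelope = c(1, rep(0, 99))), 0)
  # two-point distribution, hand-evaluated: 0.75*0.124939 + 0.25*0.602060
  expect_equal(envelope_entropy(envelope = c(0.75, 0.25)),
               -(0.75 * log10(0.75) + 0.25 * log10(0.25)), tolerance = 1e-12)
  expect_equal(envelope_entropy(envelope = c(0.75, 0.25)), 0.24422,
               tolerance = 1e-4)
  expect_error(envelope_entropy(envelope = rep(0, 10)), "zero")
  expect_error(envelope_entropy(envelope = c(1, -1)), "nonnegative")
})

test_that("envelope entropy stays within [0, log10(N)] on random signals", {
  for (seed in 1:20) {
    set.seed(seed)
    x <- rnorm(200)
    e <- envelope_entropy(x)
    expect_gte(e, 0)
    expect_lte(e, log10(200) + 1e-12)
  }
})

test_that("isolating a sparse burst component lowers the minimum envelope entropy", {
  # a burst-modulated 30 Hz component mixed with a steady 2 Hz tone: only
  # when K separates them does one mode carry the sparse envelope
  t <- seq_len(4000) / 1000
  burst <- exp(-((t - 2) / 0.15)^2) * sin(2 * pi * 30 * t)
  x <- sin(2 * pi * 2 * t) + burst
  f1 <- vmd_fitness(x, 1000, 1, 2000)
  f2 <- vmd_fitness(x, 1000, 2, 2000)
  expect_lt(f2, f1)
  # deterministic path: identical calls agree exactly
  expect_identical(f2, vmd_fitness(x, 1000, 2, 2000))
})

test_that("white-noise fitness approaches the entropy upper bound", {
  set.seed(9)
  x <- rnorm(2000)
  f <- vmd_fitness(x, 1000, 3, 2000)
  expect_gt(f, 0.8 * log10(2000))
})

test_that("DE minimizes the sphere function", {
  sphere <- function(x) sum(x^2)
  res <- de_minimize(sphere, c(-5, -5), c(5, 5),
                     de_config(pop_size = 20, F = 0.5, CR = 0.9,
                               generations = 50, patience = Inf, seed = 1))
  expect_lte(res$best_fitness, 1e-2)
  trace <- res$trace$best_fitness_per_generation
  expect_true(all(diff(trace) <= 0))
})

test_that("DE is deterministic given a seed and respects bounds", {
  fx <- two_tone_fixture()
  x <- fx$x[1:2000]
  cfg <- de_config(pop_size = 6, generations = 4, seed = 33)
  seen <- new.env(); seen$params <- list()
  fn_spy <- function(v) {
    seen$params[[length(seen$params) + 1]] <- v
    vmd_fitness(x, fx$rate, v[1], v[2], vmd_config(max_iter = 50))
  }
  r1 <- de_minimize(fn_spy, c(2, 100), c(8, 10000), cfg, integer_dims = 1)
  for (p in seen$params) {
    expect_true(p[1] >= 2 && p[1] <= 8 && p[1] == round(p[1]))
    expect_true(p[2] >= 100 && p[2] <= 10000)
  }
  r2 <- de_optimize(x, fx$rate, cfg, vmd_config(max_iter = 50))
  r3 <- de_optimize(x, fx$rate, cfg, vmd_config(max_iter = 50))
  expect_identical(r2$chosen_K, r3$chosen_K)
  expect_identical(r2$chosen_alpha, r3$chosen_alpha)
  expect_identical(r2$trace$best_fitness_per_generation,
                   r3$trace$best_fitness_per_generation)
  expect_error(de_config(pop_size = 3), "pop_size")
})

test_that("IMF band classification follows the energy centroid", {
  imfs <- rbind(tone(2, 2), tone(30, 2), tone(200, 2))
  d <- structure(list(imfs = imfs, center_freqs_hz = c(2, 30, 200),
                      residual = rep(0, 2000), n_iters = 1L, converged = TRUE,
                      rel_recon_error = 0, method = "vmd"),
                 class = "decomposition_result")
  expect_equal(classify_imfs(d, 1000),
               c("PSEUDO_ACCELERATION", "MMG", "NOISE"))
  # closed band edge: a 10 Hz tone is MMG
  d10 <- structure(list(imfs = matrix(tone(10, 2), 1), method = "vmd"),
                   class = "decomposition_result")
  expect_equal(classify_imfs(d10, 1000), "MMG")
  dz <- structure(list(imfs = matrix(0, 1, 2000), method = "vmd"),
                  class = "decomposition_result")
  expect_equal(classify_imfs(dz, 1000), "NOISE")
})

test_that("extraction partitions the IMF sum and rejects out-of-band input", {
  sr <- small_synthetic(seed = 21)
  ch <- sr$ground_truth$primary_axis[1]
  x <- sr$recording$raw_accel$samples[ch, ]
  ex <- extract_mmg(x, 1000, de_config(pop_size = 6, generations = 5, seed = 4),
                    tune_seconds = 3, fitness_max_iter = 80)
  total <- ex$mmg + ex$pseudo_acceleration + ex$noise_rejected
  expect_equal(total, colSums(ex$decomposition$imfs), tolerance = 1e-12)
  expect_equal(length(ex$imf_labels), ex$chosen_K)
  expect_true(all(diff(ex$fitness$best_fitness_per_generation) <= 1e-12))
  expect_gt(cor(ex$mmg, sr$ground_truth$mmg[ch, ]), 0.8)

  # a pure 1 Hz sinusoid has nothing in the MMG band
  x1 <- tone(1, 4)
  ex1 <- extract_mmg(x1, 1000, de_config(pop_size = 6, generations = 4, seed = 5),
                     tune_seconds = 3, fitness_max_iter = 80)
  expect_lt(sum(ex1$mmg^2) / sum(x1^2), 0.05)
})

test_that("extraction with one seed is bitwise reproducible", {
  sr <- small_synthetic(seed = 22, duration_s = 6)
  x <- sr$recording$raw_accel$samples[1, ]
  cfg <- de_config(pop_size = 5, generations = 3, seed = 17)
  e1 <- extract_mmg(x, 1000, cfg, tune_seconds = 2, fitness_max_iter = 60)
  e2 <- extract_mmg(x, 1000, cfg, tune_seconds = 2, fitness_max_iter = 60)
  expect_identical(serialize(e1, NULL), serialize(e2, NULL))
})
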