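test_that("window counting follows floor((n - w)/s) + 1", {
  cfg <- windowing_config()
  expect_equal(count_windows(5000, 1000, cfg), 21L)
  expect_equal(count_windows(1000, 1000, cfg), 1L)
  expect_equal(count_windows(999, 1000, cfg), 0L)
  # the default overlap is 800 ms
  expect_equal(cfg$window_ms - cfg$step_ms, 800)
})

test_that("build_dataset emits sub-window means with the right shapes", {
  rate <- 1000
  n <- 5000
  feats <- signal_trace(matrix(2.5, 8, n), rate, paste0("f", 1:8))
  targs <- signal_trace(matrix(rnorm(3 * n), 3, n), rate, paste0("t", 1:3))
  ds <- build_dataset(feats, targs, windowing_config())
  expect_equal(dim(ds$X), c(21, 20, 8))
  expect_equal(dim(ds$y), c(21, 20, 3))
  expect_true(all(ds$X == 2.5))
  expect_true(all(ds$mask))
})

test_that("sub-window means of a ramp form the expected arithmetic sequence", {
  rate <- 1000
  ramp <- seq(0, 1, length.out = 1000)  # one exact window
  feats <- signal_trace(matrix(ramp, 1, 1000), rate, "ramp")
  ds <- build_dataset(feats, feats, windowing_config())
  means <- ds$X[1, , 1]
  # mean of samples ((j-1)*50+1):(j*50) of a 0..1 ramp over 1000 samples
  expected <- (seq(0, 19) * 50 + (0 + 49) / 2) / 999
  expect_equal(means, expected, tolerance = 1e-12)
  expect_equal(means[1], mean(ramp[1:50]))
  expect_equal(means[20], mean(ramp[951:1000]))
  expect_lt(abs(means[1] - 1 / 40), 1e-3)
  expect_lt(abs(means[20] - 39 / 40), 1e-3)
})

test_that("build_dataset is shift-consistent at one step", {
  rate <- 1000
  set.seed(8)
  x <- matrix(rnorm(2 * 3000), 2, 3000)
  y <- matrix(rnorm(3000), 1, 3000)
  cfg <- windowing_config()
  ds1 <- build_dataset(signal_trace(x, rate), signal_trace(y, rate, "t"), cfg)
  ds2 <- build_dataset(signal_trace(x[, -(1:200)], rate),
                       signal_trace(y[, -(1:200), drop = FALSE], rate, "t"), cfg)
  # shifting by one step drops the first example; the rest coincide
  expect_equal(ds2$X[1:(dim(ds2$X)[1]), , ],
               ds1$X[2:(dim(ds1$X)[1]), , ], tolerance = 1e-12)
})

test_that("build_dataset validates alignment", {
  a <- signal_trace(matrix(0, 1, 2000), 1000)
  b <- signal_trace(matrix(0, 1, 2000), 500, "t")
  expect_error(build_dataset(a, b), "rate")
  c_short <- signal_trace(matrix(0, 1, 1000), 1000, "t")
  expect_error(build_dataset(a, c_short), "duration")
})

test_that("padding masks mark valid prefixes and reject overlong inputs", {
  m <- make_padding_mask(c(20L), 20L)
  expect_true(all(m))
  expect_equal(make_padding_mask(3L, 5L)[1, ], c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(sum(make_padding_mask(0L, 4L)), 0)
  expect_error(make_padding_mask(6L, 5L), "exceeds")
})

test_that("by-example splits are disjoint, exhaustive and seed-stable", {
  ds <- linear_fixture(n = 100)
  sp <- split_dataset(ds, 0.2, "by_example", seed = 3)
  expect_equal(n_examples(sp$train), 80L)
  expect_equal(n_examples(sp$test), 20L)
  sp2 <- split_dataset(ds, 0.2, "by_example", seed = 3)
  expect_identical(sp$test$start_sample, sp2$test$start_sample)
  expect_length(intersect(sp$train$start_sample, sp$test$start_sample), 0)
  expect_error(split_dataset(ds, 1.2), "test_fraction")
})

test_that("block splits leave no source-time overlap between train and test", {
  rate <- 1000
  feats <- signal_trace(matrix(rnorm(8 * 8000), 8, 8000), rate, paste0("f", 1:8))
  targs <- signal_trace(matrix(rnorm(8000), 1, 8000), rate, "t")
  ds <- build_dataset(feats, targs, windowing_config())
  sp <- split_dataset(ds, 0.2, "by_block", seed = 1)
  w <- ds$window_samples
  for (i in seq_len(n_examples(sp$test))) {
    t0 <- sp$test$start_sample[i]
    overlap <- sp$train$start_sample < (t0 + w) &
      (sp$train$start_sample + w) > t0
    expect_false(any(overlap))
  }
})

test_that("dataset invariants are re-validated on load", {
  ds <- linear_fixture(n = 30)
  path <- withr::local_tempfile(fileext = ".bundle")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_identical(back$X, ds$X)
  expect_identical(back$trial_id, ds$trial_id)
  # corrupt the bundle: NaN must be caught
  b <- read_bundle(path)
  b$X[1] <- NaN
  write_bundle(b, path)
  expect_error(read_dataset(path), "NaN")
})
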