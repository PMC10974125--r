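test_that("signal_trace enforces its invariants", {
  m <- rbind(sin(1:50), cos(1:50))
  tr <- signal_trace(m, 100, c("x", "y"), "m/s^2")
  expect_equal(n_channels(tr), 2L)
  expect_equal(n_samples(tr), 50L)
  expect_equal(duration_s(tr), 0.5)
  expect_error(signal_trace(m, -5), "positive")
  expect_error(signal_trace(m, 100, c("x", "x")), "unique")
  expect_error(signal_trace(matrix(0, 0, 5), 100), "channel")
  expect_equal(trace_channel(tr, "y"), cos(1:50))
  expect_error(trace_channel(tr, "nope"), "unknown channel")
})

test_that("recording requires aligned traces", {
  a <- signal_trace(matrix(0, 1, 100), 100)
  b <- signal_trace(matrix(0, 1, 100), 200)
  expect_error(recording(a, b, a), "rate")
  c50 <- signal_trace(matrix(0, 1, 50), 100)
  expect_error(recording(a, a, c50), "duration")
  expect_s3_class(recording(a, a, a), "recording")
})

test_that("CSV round trip preserves samples to 1e-12 relative and the rate", {
  tr <- signal_trace(rbind(rnorm(37), rnorm(37), rnorm(37)), 1000,
                     c("a", "b", "c"), "mV")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$rate_hz, 1000)
  expect_equal(back$channel_names, c("a", "b", "c"))
  expect_lt(rel_err(back$samples, tr$samples), 1e-12)
})

test_that("bundle round trip is bit-exact", {
  tr <- signal_trace(matrix(rnorm(60), 3, 20), 123.456,
                     c("p", "q", "r"), c("u1", "u2", "u3"))
  path <- withr::local_tempfile(fileext = ".bundle")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_identical(back$samples, tr$samples)
  expect_identical(back$rate_hz, tr$rate_hz)
  expect_identical(back$units, tr$units)
})

test_that("CSV reader reports malformed rows and non-numeric cells by index", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# rate_hz=1000", "a,b,c", "1,2,3", "4,5", "6,7,8"), path)
  expect_error(read_trace(path), "row 2")
  writeLines(c("# rate_hz=1000", "a,b", "1,2", "3,oops"), path)
  expect_error(read_trace(path), "row 2")
  writeLines(c("a,b", "1,2"), path)
  expect_error(read_trace(path), "rate")
  expect_equal(read_trace(path, rate_hz = 50)$rate_hz, 50)
})

test_that("CSV dialect is fixed: dot decimals, comma delimiter, LF endings", {
  tr <- signal_trace(matrix(c(0.5, -1.25), 2, 1), 1000, c("u", "v"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  raw <- readChar(path, file.size(path))
  expect_false(grepl("\r", raw))
  expect_match(raw, "0.5,-1.25", fixed = TRUE)
  expect_match(raw, "# rate_hz=1000", fixed = TRUE)
})

test_that("config resolution fills defaults, rejects unknown keys, is idempotent", {
  cfg <- resolve_config()
  expect_equal(cfg$model$batch_size, 64L)
  expect_equal(cfg$model$n_heads, 2L)
  expect_equal(cfg$model$n_layers, 1L)
  expect_equal(cfg$windowing$seq_len, 20L)
  over <- resolve_config(list(model = list(n_heads = 4)))
  expect_equal(over$model$n_heads, 4L)
  expect_equal(over$model$batch_size, 64L)
  expect_error(resolve_config(list(model = list(n_headz = 4))), "model.n_headz")
  expect_error(resolve_config(list(model = list(n_heads = "two"))), "numeric")
  expect_identical(resolve_config(over), over)
})

test_that("config files load from YAML and JSON", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines("model:\n  n_heads: 4\nde:\n  pop_size: 20", yml)
  cfg <- load_config(yml)
  expect_equal(cfg$model$n_heads, 4L)
  expect_equal(cfg$de$pop_size, 20L)
  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"model": {"dropout": 0.2}}', js)
  expect_equal(load_config(js)$model$dropout, 0.2)
  expect_equal(load_config(NULL), default_config())
})
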