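test_that("make_sequence sorts, validates and sets duration", {
  map <- fix_map8()
  s <- make_sequence(NULL, map)
  expect_s3_class(s, "pulse_sequence")
  expect_equal(nrow(s$pulses), 0)
  expect_equal(s$duration, 0)

  df <- data.frame(time = c(0.01, 0.0), channel = c(6L, 8L),
                   magnitude = c(0.5, 0.25))
  s2 <- make_sequence(df, map)
  expect_equal(s2$pulses$time, c(0.0, 0.01))
  expect_equal(s2$pulses$channel, c(8L, 6L))
  expect_equal(s2$duration, 0.01 + 1 / map$rate)

  expect_error(make_sequence(data.frame(time = 0, channel = 6L, magnitude = 1.2), map),
               "magnitude 1.2 outside")
  expect_error(make_sequence(data.frame(time = 0, channel = 7L, magnitude = 0.5), map),
               "not in map")
  expect_error(make_sequence(data.frame(time = -1, channel = 6L, magnitude = 0.5), map),
               "finite and >= 0")
})

test_that("equal-time ties follow within-cycle stimulation order", {
  map <- fix_map8()  # default order: apex (20) to base (6)
  df <- data.frame(time = 0.1, channel = c(6L, 20L, 12L), magnitude = 0.5)
  s <- make_sequence(df, map, validate_interleaving = FALSE)
  expect_equal(s$pulses$channel, c(20L, 12L, 6L))
})

test_that("interleaving violations are rejected", {
  map <- fix_map8()  # pulse width = 2*25 + 8 = 58 us
  close_pair <- data.frame(time = c(0.1, 0.1 + 20e-6), channel = c(20L, 18L),
                           magnitude = 0.5)
  expect_error(make_sequence(close_pair, map), "interleaving violation")
  same_time <- data.frame(time = 0.1, channel = c(20L, 18L), magnitude = 0.5)
  expect_error(make_sequence(same_time, map), "interleaving violation")
  # same-channel refractory spacing is not an interleaving matter
  ok <- data.frame(time = c(0.1, 0.1 + 58e-6), channel = c(20L, 18L),
                   magnitude = 0.5)
  expect_s3_class(make_sequence(ok, map), "pulse_sequence")
})

test_that("to_cu maps the dynamic range linearly and monotonically", {
  expect_identical(to_cu(0, 100, 200), 100L)
  expect_identical(to_cu(1, 100, 200), 200L)
  expect_identical(to_cu(0.5, 100, 200), 150L)
  expect_error(to_cu(0.5, 200, 100), "c_level must be >= t_level")
  expect_error(to_cu(1.5, 100, 200), "magnitude")
  mags <- seq(0, 1, length.out = 101)
  cu <- to_cu(mags, 120, 210)
  expect_true(all(diff(cu) >= 0))
  expect_true(all(cu >= 120 & cu <= 210))
})

test_that("electrodogram files round-trip losslessly", {
  map <- fix_map8()
  set.seed(11)
  n <- 40
  df <- data.frame(
    time = round(sort(runif(n, 0, 0.5)) * 1e6) * 1e-6,
    channel = sample(map$electrodes, n, replace = TRUE),
    magnitude = round(runif(n), 6)
  )
  df$cu <- to_cu(df$magnitude, 100, 200)
  s <- make_sequence(df, map, validate_interleaving = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_electrodogram(s, path)
  s2 <- read_electrodogram(path)
  expect_equal(s2$pulses$time, s$pulses$time, tolerance = 1e-12)
  expect_identical(s2$pulses$channel, s$pulses$channel)
  expect_equal(s2$pulses$magnitude, s$pulses$magnitude, tolerance = 1e-12)
  expect_identical(s2$pulses$cu, s$pulses$cu)
  expect_equal(s2$map$rate, map$rate)
  expect_equal(s2$map$t_levels, map$t_levels)
})

test_that("electrodogram parsing handles empty and malformed input", {
  map <- fix_map8()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_electrodogram(make_sequence(NULL, map), path)
  s <- read_electrodogram(path)
  expect_equal(nrow(s$pulses), 0)

  lines <- readLines(path)
  writeLines(c(lines, "abc\t6\t0.5\t150"), path)
  expect_error(read_electrodogram(path), "non-numeric time")
  writeLines(c(lines, "1000\t6\t0.5"), path)
  expect_error(read_electrodogram(path), "expected 4 tab-separated fields")
})

test_that("pulse_counts distinguishes stimulating pulses from slots", {
  map <- fix_map8()
  empty <- make_sequence(NULL, map)
  expect_equal(pulse_counts(empty)$total, 0)
  expect_true(all(pulse_counts(empty)$per_channel == 0))

  df <- data.frame(time = c(0, 1, 2, 3) * 1e-3, channel = c(6L, 6L, 8L, 8L),
                   magnitude = c(0.5, 0, 0.2, 0.1))
  s <- make_sequence(df, map, validate_interleaving = FALSE)
  pc <- pulse_counts(s)
  expect_equal(pc$total, 3)
  expect_equal(unname(pc$per_channel[c("6", "8")]), c(1L, 2L))
  expect_equal(pulse_counts(s, stimulating_only = FALSE)$total, 4)
  expect_equal(pc$total, sum(pc$per_channel))
})

test_that("channel maps validate their configuration", {
  expect_error(channel_map(c(6, 6, 8), 900, 25), "duplicate")
  expect_error(channel_map(1:4, 900, 25, t_levels = 150, c_levels = 100),
               "c_levels must be >= t_levels")
  expect_error(channel_map(1:4, 900, 25, n_maxima = 5), "n_maxima")
  # 62 us phases at 900 pps: only 7 pulses fit per cycle
  expect_error(channel_map(c(6, 8, 10, 12, 14, 16, 18, 20), 900, 62,
                           n_maxima = 8), "only 7 fit")
  expect_s3_class(channel_map(c(8, 10, 12, 14, 16, 18, 20), 900, 62),
                  "channel_map")
})

test_that("channel maps load from YAML configuration", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "electrodes: [6, 8, 10, 12, 14, 16, 18, 20]",
    "rate: 900", "phase_us: 25", "ipg_us: 8",
    "t_levels: [100, 100, 100, 100, 110, 110, 110, 110]",
    "c_levels: 200", "n_maxima: 8", "mode: MP1+2"), path)
  m <- read_channel_map(path)
  expect_s3_class(m, "channel_map")
  expect_equal(m$rate, 900)
  expect_equal(m$t_levels, c(rep(100, 4), rep(110, 4)))
  writeLines("rate: 900", path)
  expect_error(read_channel_map(path), "missing fields")
})

test_that("WAV files round-trip in PCM16 and float32", {
  a <- gen_tone(1000, 0.05, rate = 16000, amplitude = 0.5)
  p16 <- withr::local_tempfile(fileext = ".wav")
  p32 <- withr::local_tempfile(fileext = ".wav")
  write_wav(a, p16, bits = 16)
  write_wav(a, p32, bits = 32)
  b16 <- read_wav(p16)
  b32 <- read_wav(p32)
  expect_equal(b16$rate, 16000)
  expect_equal(b16$samples, a$samples, tolerance = 1e-4)   # 16-bit quantization
  expect_equal(b32$samples, a$samples, tolerance = 1e-7)   # float32 precision
})
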