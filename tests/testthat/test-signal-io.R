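# Reading, cleaning, framing and resampling of EDA recordings.

test_that("CSV reading infers the rate and enforces the format contract", {
  t <- seq(0, by = 0.125, length.out = 1440)
  y <- 1.5 + 0.01 * sin(t)
  rec <- read_eda_csv(write_eda_fixture(t, y))
  expect_s3_class(rec, "eda_recording")
  expect_length(rec$samples, 1440)
  expect_equal(rec$rate, 8, tolerance = 1e-9)

  # empty file
  empty <- tempfile(fileext = ".csv")
  writeLines("time_s,eda_us", empty)
  expect_error(read_eda_csv(empty), "empty")

  # non-monotonic timestamps
  expect_error(read_eda_csv(write_eda_fixture(c(0, 0.125, 0.120, 0.250),
                                              rep(1, 4))),
               "increasing")

  # irregular spacing beyond 1% jitter
  tj <- c(seq(0, by = 0.125, length.out = 100))
  tj[50] <- tj[50] + 0.05
  expect_error(read_eda_csv(write_eda_fixture(sort(tj), rep(1, 100))),
               "jitter|irregular")

  expect_error(read_eda_csv(tempfile()), "not found")
})

test_that("EDA CSV writing round-trips through reading", {
  rec <- eda_recording(seq(1, 2, length.out = 160), rate = 8)
  path <- tempfile(fileext = ".csv")
  write_eda_csv(rec, path)
  back <- read_eda_csv(path)
  expect_equal(back$samples, rec$samples, tolerance = 1e-9)
  expect_equal(back$rate, 8, tolerance = 1e-9)
})

test_that("low-pass cleaning matches the Butterworth frequency response", {
  # DC: a constant passes unchanged
  const <- eda_recording(rep(0.5, 800), rate = 8)
  out <- lowpass_filter(const)
  expect_lt(max(abs(out$samples - 0.5)), 1e-9)

  # independent oracle: squared magnitude response (forward-backward
  # application) of the designed filter, evaluated from its coefficients
  gain2 <- function(f_hz, rate = 8, cutoff = 3, order = 4) {
    bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
    w <- 2 * pi * f_hz / rate
    z <- exp(-1i * w * (seq_along(bf$b) - 1))
    Mod(sum(bf$b * z) / sum(bf$a * z))^2
  }
  measure <- function(freq) {
    rec <- sine_recording(freq, duration_s = 120)
    filt <- lowpass_filter(rec)
    mid <- 241:(length(rec$samples) - 240)
    stats::sd(filt$samples[mid]) / stats::sd(rec$samples[mid])
  }
  expect_equal(measure(0.5), gain2(0.5), tolerance = 0.01)
  expect_gt(measure(0.5), 0.99)          # passband: SCR content preserved
  expect_equal(measure(3.9), gain2(3.9), tolerance = 0.02)
  expect_lt(measure(3.9), 0.10)          # near-Nyquist noise suppressed

  # cutoff at or above Nyquist is rejected
  expect_error(lowpass_filter(const, filter_spec(cutoff = 4)), "Nyquist")
})

test_that("filtering commutes with constant offsets", {
  rec <- sine_recording(0.3, duration_s = 60, amp = 0.2, offset = 1.2)
  shifted <- eda_recording(rec$samples + 3, rate = rec$rate)
  a <- lowpass_filter(rec)$samples
  b <- lowpass_filter(shifted)$samples
  expect_lt(max(abs(b - (a + 3))), 1e-9)
})

test_that("framing cuts non-overlapping 3-minute windows and drops the tail", {
  rec <- eda_recording(seq_len(1800 * 8) / 1e4, rate = 8)
  frames <- frame_signal(rec)
  expect_length(frames, 10)
  expect_true(all(vapply(frames, length, integer(1)) == 1440))
  # frames concatenate to a prefix of the recording
  expect_equal(unlist(lapply(frames, `[[`, "samples")),
               rec$samples[1:(10 * 1440)])

  short <- eda_recording(rep(1, 185 * 8), rate = 8)
  expect_length(frame_signal(short), 1)
  expect_error(frame_signal(eda_recording(rep(1, 100 * 8), rate = 8)),
               "too short")
})

test_that("resampling is linear interpolation that preserves span and lines", {
  rec <- eda_recording(rep(1.5, 1440), rate = 8)
  expect_identical(resample_eda(rec, 8)$samples, rec$samples)

  # lines are reproduced exactly
  t8 <- seq(0, 179.875, by = 1 / 8)
  ramp <- eda_recording(1 + 0.002 * t8, rate = 8)
  up <- resample_eda(ramp, 24)
  t24 <- (seq_along(up$samples) - 1) / 24
  expect_equal(up$samples, 1 + 0.002 * t24, tolerance = 1e-12)
  expect_equal(up$rate, 24)
  expect_equal(duration(up), 180, tolerance = 1e-9)

  # round trip error is bounded by the local curvature
  wig <- eda_recording(1.5 + 0.1 * sin(2 * pi * 0.2 * t8), rate = 8)
  back <- resample_eda(resample_eda(wig, 24), 8)
  curv <- max(abs(diff(diff(wig$samples))))
  expect_lt(max(abs(back$samples - wig$samples)), 2 * curv)
})

test_that("decomposition CSV has the standard four columns", {
  fr <- eda_frame(rep(1.5, 1440), rate = 8)
  dec <- detrend_decompose(fr)
  path <- tempfile(fileext = ".csv")
  write_decomposition_csv(fr, dec, path)
  df <- utils::read.csv(path)
  expect_named(df, c("time_s", "eda_us", "tonic_us", "phasic_us"))
  expect_equal(df$tonic_us + df$phasic_us, df$eda_us, tolerance = 1e-9)
})
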