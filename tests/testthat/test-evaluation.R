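# Peak detection, slope features, divergences and the comparison report.

test_that("peak detection finds isolated SCRs and nothing on monotone data", {
  expect_length(detect_peaks(seq(0, 1, length.out = 500))$indices, 0)

  ph <- pulse_phasic(90, 0.5)
  pk <- detect_peaks(ph, rate = 8)
  expect_length(pk$indices, 1)
  # brute-force local-maximum oracle
  oracle <- which(ph[2:1439] > ph[1:1438] & ph[2:1439] > ph[3:1440]) + 1L
  expect_identical(pk$indices, oracle)
  expect_equal(pk$amplitudes, ph[pk$indices])
  # peak sits one kernel time-to-peak after the 90 s onset
  expect_equal(pk$indices / 8, 90 + bateman_peak_time(), tolerance = 0.2)

  pk2 <- detect_peaks(pulse_phasic(c(60, 90), c(0.5, 0.5)), rate = 8)
  expect_length(pk2$indices, 2)
})

test_that("peak detection respects prominence and separation thresholds", {
  ph <- pulse_phasic(c(60, 90), c(0.5, 0.005))
  expect_length(detect_peaks(ph, rate = 8, min_amplitude = 0.01)$indices, 1)
  # two merged pulses 0.5 s apart: only the larger survives separation
  ph2 <- pulse_phasic(c(60, 60.5), c(0.5, 0.4))
  pk2 <- detect_peaks(ph2, rate = 8, min_separation = 2)
  expect_length(pk2$indices, 1)
})

test_that("tonic slope and its binning follow the band boundaries", {
  t <- seq(0, 179.875, by = 1 / 8)
  expect_equal(tonic_slope(1 + 0.002 * t), 0.002 * 179.875 / 180)
  expect_equal(tonic_slope(rep(2, 1440)), 0)
  expect_equal(tonic_slope(seq(1, 1.36, length.out = 1440)), 0.002)

  expect_equal(as.character(bin_slope(-0.002)), "falling")
  expect_equal(as.character(bin_slope(0)), "stable")
  expect_equal(as.character(bin_slope(0.0015)), "rising")
  # closed stable band at both boundaries
  expect_equal(as.character(bin_slope(c(-0.001, 0.001))),
               c("stable", "stable"))
})

test_that("slope binning is monotone in the slope", {
  s <- sort(stats::runif(200, -0.01, 0.01))
  labs <- bin_slope(s)
  expect_true(all(diff(as.integer(labs)) >= 0))
})

test_that("relative entropy reproduces the published slope-histogram values", {
  u <- rep(1 / 3, 3)
  expect_equal(relative_entropy(c(0.36, 0.32, 0.32), u), 16e-4,
               tolerance = 0.5e-4 / 16e-4)
  expect_equal(relative_entropy(c(0.38, 0.30, 0.32), u), 51e-4,
               tolerance = 0.5e-4 / 51e-4)
  expect_equal(relative_entropy(c(0.38, 0.35, 0.27), u), 10e-3,
               tolerance = 0.5e-3 / 10e-3)
  expect_equal(relative_entropy(c(0.34, 0.34, 0.32), u), 40e-5,
               tolerance = 0.5e-5 / 40e-5)
  expect_equal(relative_entropy(c(0.34, 0.31, 0.35), u), 13e-4,
               tolerance = 0.5e-4 / 13e-4)
  expect_equal(relative_entropy(u, u), 0)
})

test_that("KL divergence is non-negative and zero only at equality", {
  set.seed(1)
  for (i in 1:50) {
    p <- stats::runif(4); p <- p / sum(p)
    q <- stats::runif(4); q <- q / sum(q)
    expect_gte(relative_entropy(p, q), 0)
  }
  p <- c(0.2, 0.3, 0.5)
  expect_equal(relative_entropy(p, p), 0)
  expect_error(relative_entropy(c(0.5, 0.5), c(1, 0)), "zero mass")
  expect_error(relative_entropy(c(0.9, 0.9), c(0.5, 0.5)), "sums")
})

test_that("Jensen-Shannon distance is a bounded metric", {
  p <- c(0.2, 0.8); q <- c(0.7, 0.3)
  expect_equal(jensen_shannon_distance(p, p), 0)
  expect_equal(jensen_shannon_distance(p, q),
               jensen_shannon_distance(q, p))
  expect_equal(jensen_shannon_distance(c(1, 0), c(0, 1)), sqrt(log(2)),
               tolerance = 1e-12)
  set.seed(2)
  for (i in 1:50) {
    h <- replicate(3, { v <- stats::runif(5); v / sum(v) },
                   simplify = FALSE)
    d12 <- jensen_shannon_distance(h[[1]], h[[2]])
    d13 <- jensen_shannon_distance(h[[1]], h[[3]])
    d23 <- jensen_shannon_distance(h[[2]], h[[3]])
    expect_lte(d12, d13 + d23 + 1e-12)
    expect_lte(d12, sqrt(log(2)) + 1e-12)
    expect_gte(d12, 0)
  }
  # base-2 option rescales the bound to 1
  expect_equal(jensen_shannon_distance(c(1, 0), c(0, 1), base = 2), 1,
               tolerance = 1e-12)
})

test_that("report histograms use the fixed bin families", {
  h <- peak_count_histogram(c(11, 3, 17))
  expect_equal(sum(h), 1, tolerance = 1e-9)
  expect_equal(unname(h["10-14"]), 1 / 3)
  expect_equal(unname(peak_count_histogram(11)["10-14"]), 1)

  ha <- peak_amplitude_histogram(c(0.25, 0.001))
  expect_equal(unname(ha["0.2-0.4"]), 0.5)
  expect_equal(unname(ha["0-0.005"]), 0.5)

  hr <- phasic_range_histogram(c(0.03, 0.7, 20))
  expect_equal(unname(hr["0.02-0.05"]), 1 / 3)
  expect_equal(unname(hr["0.5-1"]), 1 / 3)
  expect_equal(unname(hr["10+"]), 1 / 3)

  expect_error(peak_count_histogram(numeric(0)), "no values")
  expect_error(peak_amplitude_histogram(c(-0.1)), "non-negative")
})

test_that("compare_methods assembles a coherent report", {
  sfs <- synthesize_frames(6, sim_config(seed = 3))
  frames <- lapply(sfs, `[[`, "frame")
  pool_dec <- function(fr) {
    tn <- scl_branch(fr, 481)
    eda_decomposition(tn, fr$samples - tn, method = "pool")
  }
  rep <- compare_methods(frames,
                         list(theil = detrend_decompose,
                              pool = pool_dec,
                              pool2 = pool_dec))
  for (m in names(rep$methods)) {
    pm <- rep$methods[[m]]
    expect_equal(sum(pm$slope_histogram), 1, tolerance = 1e-9)
    expect_equal(sum(pm$peak_count_histogram), 1, tolerance = 1e-9)
    expect_equal(sum(pm$phasic_range_histogram), 1, tolerance = 1e-9)
    expect_gte(pm$slope_entropy, 0)
  }
  J <- rep$js_peak_count
  expect_equal(J, t(J))
  expect_true(all(diag(J) == 0))
  # identical decomposers are at distance zero
  expect_equal(J["pool", "pool2"], 0)
  expect_equal(rep$js_peak_amplitude["pool", "pool2"], 0)
})

test_that("a failing decomposer is excluded and logged, not fatal", {
  sfs <- synthesize_frames(3, sim_config(seed = 6))
  frames <- lapply(sfs, `[[`, "frame")
  flaky <- local({
    n <- 0
    function(fr) {
      n <<- n + 1
      if (n == 2) stop("backend hiccup")
      detrend_decompose(fr)
    }
  })
  expect_warning(
    rep <- compare_methods(frames, list(theil = detrend_decompose,
                                        flaky = flaky)),
    "excluded")
  expect_equal(nrow(rep$failures), 1)
  expect_equal(rep$failures$method, "flaky")
})

test_that("event recall scores known events against a phasic estimate", {
  sf <- synthesize_frame(sim_config(seed = 44, noise_sd = 0))
  r <- event_recall(sf, sf$phasic_truth, min_true_amplitude = 0.1,
                    min_detected_amplitude = 0.05)
  if (r$n_events > 0) expect_equal(r$recall, 1)
  # a zero phasic recovers nothing
  r0 <- event_recall(sf, numeric(1440), min_true_amplitude = 0.1)
  if (r0$n_events > 0) expect_equal(r0$recall, 0)
})
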