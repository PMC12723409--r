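test_that("averaging keeps a common waveform and cancels opposite channels", {
  fs <- 10000
  n <- 1200
  stim <- 600
  wave <- sin(seq(0, 6 * pi, length.out = n))
  data <- array(0, c(5, 2, n))
  for (tr in 1:5) for (ch in 1:2) data[tr, ch, ] <- wave
  trace <- lfp_trace(data, fs, stim)
  out <- average_and_baseline(trace)
  i0 <- stim + round(-50 * fs / 1e3); i1 <- stim
  expect_equal(out, wave - mean(wave[i0:i1]), tolerance = 1e-12)
  data2 <- data
  data2[, 2, ] <- -data2[, 1, ]
  expect_equal(average_and_baseline(lfp_trace(data2, fs, stim)), rep(0, n))
})

test_that("trial averaging reduces noise by the square-root law", {
  set.seed(12)
  fs <- 10000; n <- 1200; stim <- 600
  template <- 10 * exp(-((seq_len(n) - stim) / fs * 1e3 - 5.6)^2 / 2)
  data <- array(rnorm(100 * 1 * n, sd = 4), c(100, 1, n))
  data <- sweep(data, 3, template, "+")
  avg <- average_and_baseline(lfp_trace(data, fs, stim))
  rms_avg <- sqrt(mean((avg - (template - mean(template[(stim - 500):stim])))^2))
  rms_single <- sqrt(mean((data[1, 1, ] - template)^2))
  expect_lt(rms_avg, 2.5 * rms_single / sqrt(100))
  expect_gt(rms_avg, 0.4 * rms_single / sqrt(100))
})

test_that("peak detection finds injected deflections and orders P1 first", {
  fs <- 30000
  t_ms <- seq(-30, 25, by = 1 / 30) # one-sample steps at 30 kHz
  tr <- 20 * exp(-(t_ms - 5.6)^2 / 0.5) - 40 * exp(-(t_ms - 11.8)^2 / 2)
  stim <- which.min(abs(t_ms))
  pk <- detect_peaks(tr, fs, stim)
  expect_true(pk$has_p1 && pk$has_n1)
  expect_equal(pk$p1_latency, 5.6, tolerance = 1 / 30 + 1e-9)
  expect_equal(pk$n1_latency, 11.8, tolerance = 1 / 30 + 1e-9)
  ## two positive bumps: the first wins even though the second is larger
  tr2 <- 5 * exp(-(t_ms - 3)^2 / 0.3) + 9 * exp(-(t_ms - 7)^2 / 0.3)
  pk2 <- detect_peaks(tr2, fs, stim, min_amplitude = 0)
  expect_equal(pk2$p1_latency, 3, tolerance = 1 / 30 + 1e-9)
})

test_that("flat traces yield no-P1/no-N1 flags and short records error", {
  fs <- 30000
  n <- 40 * 30
  pk <- detect_peaks(rep(0, n), fs, stim_index = 300)
  expect_false(pk$has_p1)
  expect_false(pk$has_n1)
  expect_error(detect_peaks(rep(0, 100), fs, stim_index = 50), "window")
})

test_that("latency detection is invariant to scaling and offset", {
  fs <- 20000
  t_ms <- seq(-20, 25, by = 1e3 / fs)
  tr <- 8 * exp(-(t_ms - 4.2)^2 / 0.4) - 20 * exp(-(t_ms - 12.4)^2 / 1.5)
  stim <- which.min(abs(t_ms))
  ref <- detect_peaks(tr, fs, stim)
  scaled <- detect_peaks(7.3 * tr, fs, stim)
  expect_equal(scaled$p1_latency, ref$p1_latency)
  expect_equal(scaled$n1_latency, ref$n1_latency)
  ## offsets are removed upstream by baseline correction
  data <- array(0, c(1, 2, length(tr)))
  data[1, 1, ] <- tr + 55
  data[1, 2, ] <- tr + 55
  avg <- average_and_baseline(lfp_trace(data, fs, stim,
                                        baseline_window = c(-15, 0)))
  shifted <- detect_peaks(avg, fs, stim)
  expect_equal(shifted$p1_latency, ref$p1_latency)
})

test_that("the coefficient of variation implements SD over |mean|", {
  fs <- 1000
  n <- 120
  stim <- 40
  amps <- c(-10, -10, -10, 10)
  data <- array(0, c(4, 1, n))
  idx <- stim + 10
  for (tr in 1:4) data[tr, 1, idx] <- amps[tr]
  trace <- lfp_trace(data, fs, stim, baseline_window = c(-20, 0))
  rc <- reliability_cov(trace, n1_latency = 10)
  expect_equal(rc$cov, 2.0)
  expect_false(rc$reliable)
  ## identical trials: cov 0, reliable
  data1 <- array(rep(-5, 3 * n), c(3, 1, n))
  for (tr in 1:3) data1[tr, 1, idx] <- -30
  rc1 <- reliability_cov(lfp_trace(data1, fs, stim,
                                   baseline_window = c(-20, 0)), 10)
  expect_equal(rc1$cov, 0)
  expect_true(rc1$reliable)
})

test_that("sampled CoV matches the population ratio", {
  set.seed(61)
  fs <- 1000; n <- 120; stim <- 40; idx_lat <- 10
  data <- array(0, c(200, 1, n))
  data[, 1, stim + idx_lat] <- rnorm(200, -20, 5)
  rc <- reliability_cov(lfp_trace(data, fs, stim,
                                  baseline_window = c(-20, -1)), idx_lat)
  expect_equal(rc$cov, 0.25, tolerance = 0.05)
  expect_true(rc$reliable)
})

test_that("N1 onset lies between P1 and the N1 trough", {
  fs <- 30000
  t_ms <- seq(-30, 25, by = 1 / 30)
  tr <- 20 * exp(-(t_ms - 5.6)^2 / 0.5) - 40 * exp(-(t_ms - 11.8)^2 / 2)
  stim <- which.min(abs(t_ms))
  pk <- detect_peaks(tr, fs, stim)
  on <- n1_onset(tr, fs, stim, pk)
  expect_gt(on, pk$p1_latency)
  expect_lt(on, pk$n1_latency)
})
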