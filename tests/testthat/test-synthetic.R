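test_that("diameter-law solving hits the requested mode and p90", {
  for (tg in list(c(0.31, 0.66), c(0.39, 1.42), c(0.5, 1.0))) {
    law <- solve_diameter_law(tg[1], tg[2])
    expect_equal(law$mode, tg[1], tolerance = 1e-8)
    expect_equal(law$p90, tg[2], tolerance = 1e-6)
    ln <- solve_diameter_law(tg[1], tg[2], law = "lognormal")
    expect_equal(ln$mode, tg[1], tolerance = 1e-8)
    expect_equal(ln$p90, tg[2], tolerance = 1e-8)
  }
  expect_error(solve_diameter_law(0.5, 0.4), "parameterization")
})

test_that("diameter samples reproduce the preparation calibration targets", {
  s <- gen_diameter_sample(30000, target = "epon", seed = 71)
  expect_gte(kde_mode(s$diameters), 0.25)
  expect_lte(kde_mode(s$diameters), 0.37)
  p90 <- unname(quantile(s$diameters, 0.9))
  expect_gte(p90, 0.55)
  expect_lte(p90, 0.80)
  cr <- gen_diameter_sample(10000, target = "cryo", seed = 72)
  ratio_epon <- s$truth$p90 / s$truth$mode
  ratio_cryo <- cr$truth$p90 / cr$truth$mode
  expect_gt(ratio_cryo, ratio_epon) # heavier tail by construction
})

test_that("generators are deterministic under a fixed seed", {
  a <- gen_diameter_sample(500, seed = 5)$diameters
  b <- gen_diameter_sample(500, seed = 5)$diameters
  expect_identical(a, b)
  m1 <- gen_tem_mask(5, width = 600, height = 600, pixel_size = 0.01,
                     seed = 6)
  m2 <- gen_tem_mask(5, width = 600, height = 600, pixel_size = 0.01,
                     seed = 6)
  expect_identical(m1$mask$classes, m2$mask$classes)
  g1 <- gen_dmri_signals(3, diameters = 2, snr = 50, seed = 7)
  g2 <- gen_dmri_signals(3, diameters = 2, snr = 50, seed = 7)
  expect_identical(g1$dataset$volume, g2$dataset$volume)
  l1 <- gen_lfp(n_trials = 5, seed = 8)
  l2 <- gen_lfp(n_trials = 5, seed = 8)
  expect_identical(l1$trace$data, l2$trace$data)
})

test_that("an empty mask request renders an empty mask", {
  gm <- gen_tem_mask(0, width = 200, height = 200, pixel_size = 0.01,
                     seed = 9)
  expect_true(all(gm$mask$classes == 0L))
  expect_equal(nrow(gm$truth), 0)
})

test_that("oversized packing requests fail loudly", {
  expect_error(
    gen_tem_mask(400, width = 300, height = 300, pixel_size = 0.005,
                 seed = 10),
    "packing failure")
})

test_that("noiseless cylinder voxels invert to their true diameter", {
  gen <- gen_dmri_signals(3, diameters = 4, va = 0.7, D0 = 0.6, snr = Inf,
                          axis = c(0, 0, 1), seed = 73)
  for (v in 1:3) {
    expect_equal(voxel_diameter(gen, v), 4, tolerance = 0.01)
  }
})

test_that("sub-resolution truths collapse to zero or discarded estimates", {
  gen <- gen_dmri_signals(30, diameters = 0.5, va = 0.7, D0 = 0.6, snr = 50,
                          seed = 74)
  d <- vapply(seq_len(30), function(v) voxel_diameter(gen, v), numeric(1))
  expect_gt(mean(d < 0.1), 0.5)
})

test_that("injected LFP latencies are recovered from the noisy average", {
  gl <- gen_lfp(seed = 75)
  avg <- average_and_baseline(gl$trace)
  pk <- detect_peaks(avg, gl$trace$fs, gl$trace$stim_index,
                     smooth_ms = 0.5, peak_window_ms = 1)
  expect_equal(pk$p1_latency, gl$truth$p1_ms, tolerance = 0.25)
  expect_equal(pk$n1_latency, gl$truth$n1_ms, tolerance = 0.5)
  ## with a noise-free average the strict single-sample rule is exact
  ql <- gen_lfp(noise_sd = 0, drift_amp = 0, seed = 76)
  qk <- detect_peaks(average_and_baseline(ql$trace), ql$trace$fs,
                     ql$trace$stim_index)
  expect_equal(qk$p1_latency, ql$truth$p1_ms, tolerance = 1 / 30 + 1e-9)
})

test_that("overwhelming trial noise fails the reliability criterion", {
  gl <- gen_lfp(n_trials = 30, noise_sd = 400, seed = 77)
  avg <- average_and_baseline(gl$trace)
  rc <- reliability_cov(gl$trace, gl$truth$n1_ms)
  expect_false(rc$reliable)
  ## zero-noise identical trials: cov exactly 0
  q <- gen_lfp(n_trials = 10, noise_sd = 0, drift_amp = 0,
               gain_mismatch = 0, seed = 78)
  expect_equal(reliability_cov(q$trace, q$truth$n1_ms)$cov, 0)
})
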