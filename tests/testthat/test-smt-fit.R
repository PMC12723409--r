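b3 <- c(24450, 21247, 17560)

test_that("powder averaging normalizes by b0 and means within shells", {
  bvals <- c(rep(0, 9), rep(b3, each = 30))
  sig <- c(rep(2, 9), rep(2 * c(0.5, 0.4, 0.3), each = 30))
  pw <- powder_average(sig, bvals)
  expect_equal(pw$b_shells, sort(b3))
  expect_equal(pw$sbar, c(0.3, 0.4, 0.5))
  expect_equal(pw$n_dirs, rep(30L, 3))
  expect_true(pw$valid)
})

test_that("powder average of forward-model signals equals the closed form", {
  sbar_true <- smt_powder_signal(b3, 0.7, 0.6, 0.05)
  bvals <- c(rep(0, 9), rep(b3, each = 30))
  sig <- c(rep(1, 9), rep(sbar_true, each = 30))
  pw <- powder_average(sig, bvals)
  expect_equal(pw$sbar, rev(sbar_true), tolerance = 1e-6)
})

test_that("zero b0 marks the voxel invalid", {
  pw <- powder_average(c(0, 0, 0.5, 0.4), c(0, 0, 4000, 4000))
  expect_false(pw$valid)
  expect_error(powder_average(c(0.5), c(4000)), "b0")
})

test_that("tensor fit recovers principal diffusivity", {
  dirs <- fibonacci_directions(61)
  bv <- c(rep(0, 4), rep(4000, 61))
  bvec <- rbind(matrix(0, 4, 3), dirs)
  lam <- c(1.7, 0.3, 0.3)
  quad <- colSums((t(dirs) * lam) * t(dirs))
  sig <- c(rep(1, 4), exp(-4 * quad))
  expect_equal(fit_dti_principal_diffusivity(sig, bvec, bv), 1.7,
               tolerance = 1e-6)
  iso <- c(rep(1, 4), exp(-4 * 0.9 * rowSums(dirs^2)))
  expect_equal(fit_dti_principal_diffusivity(iso, bvec, bv), 0.9,
               tolerance = 1e-6)
  ## voxel-matrix input averages the principal eigenvalues
  two <- rbind(sig, sig)
  expect_equal(fit_dti_principal_diffusivity(two, bvec, bv), 1.7,
               tolerance = 1e-6)
})

test_that("underdetermined tensor designs raise a fit error", {
  dirs5 <- fibonacci_directions(5)
  bv <- c(0, rep(4000, 5))
  bvec <- rbind(c(0, 0, 0), dirs5)
  expect_error(
    fit_dti_principal_diffusivity(rep(0.5, 6), bvec, bv),
    "6 unique")
})

test_that("noiseless generate-and-recover is exact to 1e-3", {
  for (truth in list(c(0.7, 0.05), c(0.4, 0.2), c(0.9, 0.01))) {
    pw <- make_powder(b3, smt_powder_signal(b3, truth[1], 0.6, truth[2]))
    fit <- fit_smt(pw, D0 = 0.6)
    expect_lt(abs(fit$va - truth[1]) / truth[1], 1e-3)
    expect_lt(abs(fit$Dperp - truth[2]) / truth[2], 1e-3)
    expect_true(fit$converged)
  }
})

test_that("a known signal fraction reduces the fit to one parameter", {
  dp_true <- 0.02
  pw <- make_powder(b3, smt_powder_signal(b3, 1, 0.6, dp_true))
  fit <- fit_smt(pw, D0 = 0.6, va_fixed = 1)
  expect_equal(fit$va, 1)
  expect_equal(fit$Dperp, dp_true, tolerance = 1e-6)
})

test_that("isotropic signals drive the perpendicular diffusivity to D0", {
  ## D0 low enough that the shells retain measurable signal, so the
  ## isotropic limit is identifiable rather than lost below 1e-6
  D0 <- 0.1
  pw <- make_powder(b3, 0.7 * exp(-b3 * 1e-3 * D0))
  fit <- fit_smt(pw, D0 = D0)
  expect_equal(fit$Dperp, D0, tolerance = 1e-3)
})

test_that("diameter inversion round-trips and caps out-of-range values", {
  for (d in c(2, 4, 6)) {
    dp <- effective_Dperp(d / 2, 8, 18, 0.6)
    expect_equal(as.numeric(diameter_from_Dperp(dp, 8, 18, 0.6)), d,
                 tolerance = 1e-6)
  }
  expect_equal(as.numeric(diameter_from_Dperp(0, 8, 18, 0.6)), 0)
  big <- diameter_from_Dperp(0.59, 8, 18, 0.6)
  expect_true(attr(big, "capped"))
  expect_equal(as.numeric(big), 20)
})

test_that("doubling D0 changes the inverted diameter by about 2^(1/4)", {
  for (d in c(3, 4, 5)) {
    dp <- effective_Dperp(d / 2, 8, 18, 0.6)
    d2 <- as.numeric(diameter_from_Dperp(dp, 8, 18, 1.2))
    expect_gte(d2 / d, 1.14)
    expect_lte(d2 / d, 1.25)
  }
})

test_that("ROI distribution separates zero, discarded and retained voxels", {
  out <- roi_diameter_distribution(c(1.0, 1.0, 0.05))
  expect_equal(out$n_used, 2)
  expect_equal(out$n_discarded, 1)
  expect_equal(out$stats$mean, 1.0)
  single <- roi_diameter_distribution(2.5)
  expect_equal(single$stats$mode, 2.5)
  expect_equal(single$stats$sd, 0)
  expect_error(roi_diameter_distribution(c(0, 0, 0)), "empty distribution")
  mixed <- roi_diameter_distribution(c(0, 0.04, 0.5, 1.2))
  expect_equal(mixed$n_zero, 1)
  expect_equal(mixed$frac_excluded, 0.5)
})

test_that("a small diameter map pipeline runs end to end on a dataset", {
  gen <- gen_dmri_signals(4, diameters = 4, va = 0.7, D0 = 0.6, snr = Inf,
                          axis = c(0, 0, 1), seed = 21)
  map <- fit_diameter_map(gen$dataset, protocol = protocol_diameter(),
                          D0 = 0.6)
  expect_s3_class(map, "diameter_map")
  expect_true(all(map$state == "ok"))
  expect_equal(as.numeric(map$diameter), rep(4, 4), tolerance = 0.01)
})
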