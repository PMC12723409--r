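# rasterize an axis-aligned ellipse into a class matrix
draw_ellipse <- function(cls, cx, cy, a, b, value) {
  rr <- row(cls); cc <- col(cls)
  inside <- ((cc - cx) / a)^2 + ((rr - cy) / b)^2 <= 1
  cls[inside & cls == 0L] <- value
  cls
}
draw_ring <- function(cls, cx, cy, a_in, b_in, a_out, b_out) {
  rr <- row(cls); cc <- col(cls)
  inner <- ((cc - cx) / a_in)^2 + ((rr - cy) / b_in)^2 <= 1
  outer_ <- ((cc - cx) / a_out)^2 + ((rr - cy) / b_out)^2 <= 1
  cls[outer_ & !inner] <- 2L
  cls[inner] <- 1L
  cls
}

test_that("moment ellipses recover digital disk and ellipse axes", {
  cls <- draw_ellipse(matrix(0L, 101, 101), 51, 51, 20, 20, 1L)
  el <- moments_ellipse(which(cls == 1L, arr.ind = TRUE))
  expect_equal(el$minor_px, 40, tolerance = 0.05)
  expect_lt(el$eccentricity, 0.1)
  cls2 <- draw_ellipse(matrix(0L, 101, 101), 51, 51, 30, 10, 1L)
  el2 <- moments_ellipse(which(cls2 == 1L, arr.ind = TRUE))
  expect_equal(el2$minor_px, 20, tolerance = 0.05)
  expect_equal(el2$major_px, 60, tolerance = 0.05)
  expect_equal(el2$eccentricity, sqrt(1 - (10 / 30)^2), tolerance = 0.05)
})

test_that("a measured annulus yields the constructed g-ratio", {
  cls <- draw_ring(matrix(0L, 101, 101), 51, 51, 20, 20, 30, 30)
  mask <- label_mask(cls, pixel_size = 0.005)
  res <- analyze_mask(mask, border_px = 4)
  expect_equal(nrow(res$records), 1)
  expect_equal(res$records$g, 20 / 30, tolerance = 0.02)
  expect_equal(res$records$inner_diameter, 40 * 0.005, tolerance = 0.01)
  expect_equal(res$records$myelin_coverage, 1)
})

test_that("blob analysis separates fibers and splits shared myelin", {
  cls <- matrix(0L, 60, 60)
  cls <- draw_ring(cls, 18, 30, 6, 6, 10, 10)
  cls <- draw_ring(cls, 42, 30, 6, 6, 10, 10)
  mask <- label_mask(cls, pixel_size = 0.01)
  ex <- extract_axon_instances(mask)
  expect_length(ex$candidates, 2)
  ## bridge the two sheaths: the bridge myelin must be split, not merged
  cls2 <- cls
  cls2[29:31, 26:34] <- 2L
  ex2 <- extract_axon_instances(label_mask(cls2, pixel_size = 0.01))
  expect_length(ex2$candidates, 2)
  n_my <- vapply(ex2$candidates, function(cn) nrow(cn$myelin_idx), integer(1))
  expect_true(all(n_my > 0))
  expect_equal(sum(n_my), sum(cls2 == 2L))
  ## the split is roughly even for a symmetric bridge
  expect_lt(abs(n_my[1] - n_my[2]) / sum(n_my), 0.1)
})

test_that("holes inside axons are filled before measurement", {
  cls <- draw_ring(matrix(0L, 61, 61), 31, 31, 12, 12, 18, 18)
  cls[29:33, 29:33] <- 0L # organelle-like hole
  ex <- extract_axon_instances(label_mask(cls, pixel_size = 0.01))
  expect_equal(nrow(ex$candidates[[1]]$axon_idx),
               sum(((col(cls) - 31) / 12)^2 + ((row(cls) - 31) / 12)^2 <= 1))
})

test_that("orphan myelin is counted, not measured", {
  cls <- matrix(0L, 60, 60)
  cls <- draw_ring(cls, 20, 20, 6, 6, 10, 10)
  rr <- row(cls); cc <- col(cls)
  ring2 <- ((cc - 45) / 8)^2 + ((rr - 45) / 8)^2 <= 1 &
    ((cc - 45) / 5)^2 + ((rr - 45) / 5)^2 > 1
  cls[ring2] <- 2L
  ex <- extract_axon_instances(label_mask(cls, pixel_size = 0.01))
  expect_length(ex$candidates, 1)
  expect_equal(ex$n_orphan_myelin, 1L)
})

test_that("injected violations are excluded for exactly their reason", {
  gm <- gen_tem_mask(3, target = "epon", width = 900, height = 900,
                     pixel_size = 0.01,
                     violations = c(border = 1, unmyelinated = 1,
                                    high_ecc = 1),
                     seed = 31)
  res <- filter_axon_instances(extract_axon_instances(gm$mask))
  expect_equal(unname(res$counts[["accepted"]]), 3)
  expect_equal(unname(res$counts[["border"]]), 1)
  expect_equal(unname(res$counts[["no_myelin"]]), 1)
  expect_equal(unname(res$counts[["high_eccentricity"]]), 1)
  ## conservation: accepted + per-reason exclusions = candidates
  reason_sum <- sum(res$counts[c("accepted", "no_myelin", "min_area",
                                 "border", "low_coverage",
                                 "high_eccentricity")])
  expect_equal(reason_sum, res$n_candidates)
})

test_that("an eccentricity straddling the two rule sets flips acceptance", {
  gm <- gen_tem_mask(0, target = "epon", width = 700, height = 700,
                     pixel_size = 0.01,
                     violations = c(high_ecc = 1), ecc_violation = 0.96,
                     seed = 32)
  ex <- extract_axon_instances(gm$mask)
  epon <- filter_axon_instances(ex, preparation = "epon")
  cryo <- filter_axon_instances(ex, preparation = "cryo")
  expect_equal(unname(epon$counts[["high_eccentricity"]]), 1)
  expect_equal(unname(epon$counts[["accepted"]]), 0)
  expect_equal(unname(cryo$counts[["accepted"]]), 1)
  expect_error(filter_axon_instances(ex, preparation = "osmium"),
               "config error")
})

test_that("tightening thresholds never increases the accepted count", {
  gm <- gen_tem_mask(25, target = "epon", width = 1200, height = 1200,
                     pixel_size = 0.01, seed = 33)
  ex <- extract_axon_instances(gm$mask)
  base <- filter_axon_instances(ex)
  for (cov in c(0.95, 0.99, 1)) {
    for (ecc in c(0.92, 0.5, 0.3)) {
      tight <- filter_axon_instances(ex, coverage_min = cov,
                                     eccentricity_max = ecc)
      expect_lte(tight$counts[["accepted"]], base$counts[["accepted"]])
    }
  }
})

test_that("morphometry recovers generator truth per axon", {
  gm <- gen_tem_mask(30, target = "epon", width = 1400, height = 1400,
                     pixel_size = 0.01, seed = 34)
  res <- analyze_mask(gm$mask)
  expect_equal(nrow(res$records), 30)
  tr <- gm$truth
  near <- vapply(seq_len(nrow(res$records)), function(i)
    which.min((tr$cx - res$records$cx[i])^2 +
                (tr$cy - res$records$cy[i])^2), integer(1))
  expect_lte(max(abs(res$records$inner_diameter - tr$inner_diameter[near])),
             0.01) # one pixel equivalent
  expect_lte(max(abs(res$records$g - tr$g[near])), 0.03)
})

test_that("KDE mode matches analytic modes of known laws", {
  set.seed(41)
  ## argmax jitter of a Silverman-bandwidth KDE at n = 1e5 is ~0.01-0.015
  expect_lt(abs(kde_mode(rnorm(1e5, 0.5, 0.1)) - 0.5), 0.04)
  ## on skewed laws the smoothing additionally biases the mode by a few
  ## percent of scale; gamma(k = 2) has analytic mode (k-1)*theta
  theta <- 0.5
  g <- rgamma(1e5, shape = 2, scale = theta)
  expect_lt(abs(kde_mode(g) - theta) / theta, 0.10)
  expect_equal(kde_mode(rep(0.3, 10)), 0.3)
  expect_equal(kde_mode(0.42), 0.42)
  expect_error(kde_mode(numeric(0)), "empty")
})

test_that("distribution statistics use interpolated quantiles", {
  st <- distribution_stats(1:10)
  expect_equal(st$p90, 9.1)
  expect_equal(st$mean, 5.5)
  one <- distribution_stats(2)
  expect_equal(one$mode, 2)
  expect_equal(one$p90, 2)
  expect_equal(one$sd, 0)
  expect_error(distribution_stats(numeric(0)), "empty")
})
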