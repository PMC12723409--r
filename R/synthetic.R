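#' Solve diameter-law parameters from a (mode, p90) pair
#'
#' Right-skewed axon-diameter laws parameterized by their mode and 90th
#' percentile. For the gamma law the shape k solves
#' \eqn{q_{0.9}(k)/(k-1) = p90/mode} (scale follows from the mode
#' \eqn{(k-1)\theta}); for the lognormal, \eqn{\sigma} solves
#' \eqn{\sigma^2 + z_{0.9}\sigma = \log(p90/mode)}.
#'
#' @param mode Target distribution mode, \eqn{\mu m}.
#' @param p90 Target 90th percentile, \eqn{\mu m} (must exceed the mode).
#' @param law `"gamma"` (default) or `"lognormal"`.
#' @return List: `law`, parameters (`shape`/`scale` or `meanlog`/`sdlog`),
#'   and the analytic `mode` and `p90` they reproduce.
#' @export
solve_diameter_law <- function(mode, p90, law = c("gamma", "lognormal")) {
  law <- match.arg(law)
  if (mode <= 0 || p90 <= mode)
    stop("parameterization error: need 0 < mode < p90")
  r <- p90 / mode
  if (law == "gamma") {
    f <- function(k) qgamma(0.9, shape = k) / (k - 1) - r
    lo <- 1 + 1e-6; hi <- 2
    while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
    if (hi >= 1e6) stop("parameterization error: (mode, p90) infeasible for gamma")
    k <- uniroot(f, c(lo, hi), tol = 1e-12)$root
    th <- mode / (k - 1)
    list(law = "gamma", shape = k, scale = th,
         mode = (k - 1) * th, p90 = qgamma(0.9, shape = k, scale = th))
  } else {
    z <- qnorm(0.9)
    disc <- z^2 + 4 * log(r)
    s <- (-z + sqrt(disc)) / 2
    mu <- log(mode) + s^2
    list(law = "lognormal", meanlog = mu, sdlog = s,
         mode = exp(mu - s^2), p90 = exp(mu + z * s))
  }
}

## Printed group-mean calibration targets for the two preparations
.diameter_targets <- list(epon = c(mode = 0.31, p90 = 0.66),
                          cryo = c(mode = 0.39, p90 = 1.42))

#' Draw an axon-diameter sample with known analytic summaries
#'
#' i.i.d. draws from a right-skewed diameter law calibrated to a (mode, p90)
#' target. The built-in targets are the cohort group means of the two TEM
#' preparations: `"epon"` (mode 0.31, p90 0.66 \eqn{\mu m}) and `"cryo"`
#' (mode 0.39, p90 1.42 \eqn{\mu m}).
#'
#' @param n Sample size.
#' @param target `"epon"`, `"cryo"`, or `NULL` to use `mode`/`p90`.
#' @param mode,p90 Explicit calibration targets, \eqn{\mu m}.
#' @param law `"gamma"` (default) or `"lognormal"`.
#' @param seed Optional RNG seed (same seed, same sample).
#' @return List: `diameters` (\eqn{\mu m}) and `truth` (the solved law with
#'   its analytic mode and p90).
#' @export
gen_diameter_sample <- function(n, target = "epon", mode = NULL, p90 = NULL,
                                law = "gamma", seed = NULL) {
  if (!is.null(target)) {
    tg <- .diameter_targets[[match.arg(target, names(.diameter_targets))]]
    mode <- mode %||% tg[["mode"]]
    p90 <- p90 %||% tg[["p90"]]
  }
  lawp <- solve_diameter_law(mode, p90, law)
  if (!is.null(seed)) set.seed(seed)
  d <- if (lawp$law == "gamma")
    rgamma(n, shape = lawp$shape, scale = lawp$scale)
  else
    rlnorm(n, meanlog = lawp$meanlog, sdlog = lawp$sdlog)
  list(diameters = d, truth = lawp)
}

#' Synthetic axon/myelin label mask with per-axon ground truth
#'
#' Renders non-overlapping elliptical axons with annular (confocally scaled)
#' myelin sheaths at per-axon g-ratios drawn from a clipped normal around the
#' target, plus optional injected rule violations: fibers overlapping the
#' image border, unmyelinated axons, and over-eccentric axons. The truth
#' table records each axon's diameters, g-ratio, eccentricity and violation
#' type, so filter decisions can be checked exactly.
#'
#' @param n_axons Number of clean axons.
#' @param target,mode,p90,law Diameter law, as in [gen_diameter_sample()].
#' @param g_mean,g_sd g-ratio distribution (clipped to (0.4, 0.9)); defaults
#'   0.64 and 0.04.
#' @param width,height Mask size, px.
#' @param pixel_size Pixel edge length, \eqn{\mu m} (default 0.005, a typical
#'   TEM scale for a ~25 \eqn{\mu m} field of view).
#' @param preparation `"epon"` or `"cryo"` (stored on the mask).
#' @param violations Named counts: `border`, `unmyelinated`, `high_ecc`.
#' @param ecc_violation Eccentricity given to injected high-ecc axons
#'   (default 0.98, above both preparations' thresholds).
#' @param aspect_range Major/minor axis ratio range for clean axons (default
#'   1 to 1.35, eccentricities well below the rejection thresholds).
#' @param seed Optional RNG seed.
#' @param max_attempts Placement attempts per axon before a packing error.
#' @return List: `mask` (a `label_mask`) and `truth` (data.frame with one row
#'   per rendered axon).
#' @export
gen_tem_mask <- function(n_axons, target = "epon", mode = NULL, p90 = NULL,
                         law = "gamma", g_mean = 0.64, g_sd = 0.04,
                         width = 1024, height = 1024, pixel_size = 0.005,
                         preparation = if (is.null(target)) "epon" else target,
                         violations = c(border = 0, unmyelinated = 0, high_ecc = 0),
                         ecc_violation = 0.98,
                         aspect_range = c(1, 1.35),
                         seed = NULL, max_attempts = 1000) {
  if (!is.null(seed)) set.seed(seed)
  viol <- c(border = 0, unmyelinated = 0, high_ecc = 0)
  viol[names(violations)] <- violations
  n_total <- n_axons + sum(viol)
  types <- c(rep("clean", n_axons),
             rep("border", viol[["border"]]),
             rep("unmyelinated", viol[["unmyelinated"]]),
             rep("high_ecc", viol[["high_ecc"]]))
  cls <- matrix(0L, height, width)
  truth <- list()
  if (n_total > 0) {
    gen <- gen_diameter_sample(n_total, target = target, mode = mode,
                               p90 = p90, law = law)
    ds <- gen$diameters
    ## injected violations are fixtures for the filter rules, not part of
    ## the calibrated size distribution; cap them at the law's p90 so a
    ## tail draw with a 5:1 aspect or a border overhang still fits
    ds[types != "clean"] <- pmin(ds[types != "clean"], gen$truth$p90)
    ## place the largest fibers first: packing succeeds far more often
    order_by_size <- order(ds, decreasing = TRUE)
    for (i in order_by_size) {
      type <- types[i]
      d_in <- ds[i]
      b_in <- d_in / 2 / pixel_size # semi-minor, px
      aspect <- if (type == "high_ecc") 1 / sqrt(1 - ecc_violation^2)
        else runif(1, aspect_range[1], aspect_range[2])
      a_in <- b_in * aspect
      g <- if (type == "unmyelinated") 1
        else min(0.9, max(0.4, rnorm(1, g_mean, g_sd)))
      a_out <- a_in / g; b_out <- b_in / g
      phi <- runif(1, 0, pi)
      rad <- a_out + 3
      if (2 * (rad + 5) >= min(width, height))
        stop("packing failure: axon larger than the mask; enlarge the mask")
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        if (type == "border") {
          ## center close to an edge so the sheath crosses the 4-px margin
          side <- sample(4, 1)
          along <- runif(1, rad, (if (side <= 2) width else height) - rad)
          off <- runif(1, -b_out / 2, 2)
          cx <- switch(side, along, along, off, width - off)
          cy <- switch(side, off, height - off, along, along)
        } else {
          cx <- runif(1, rad + 5, width - rad - 5)
          cy <- runif(1, rad + 5, height - rad - 5)
        }
        r0 <- max(1, floor(cy - rad)); r1 <- min(height, ceiling(cy + rad))
        c0 <- max(1, floor(cx - rad)); c1 <- min(width, ceiling(cx + rad))
        rr <- r0:r1; cc <- c0:c1
        dx <- outer(rep(1, length(rr)), cc - cx)
        dy <- outer(rr - cy, rep(1, length(cc)))
        u <- dx * cos(phi) + dy * sin(phi)
        v <- -dx * sin(phi) + dy * cos(phi)
        ## exact pixel test against everything placed so far, 2-px gap
        clash_zone <- (u / (a_out + 2))^2 + (v / (b_out + 2))^2 <= 1
        if (!any(cls[rr, cc][clash_zone] != 0L)) { ok <- TRUE; break }
      }
      if (!ok)
        stop("packing failure: could not place axon ", i,
             "; reduce n_axons or enlarge the mask")
      inside_in <- (u / a_in)^2 + (v / b_in)^2 <= 1
      block <- cls[rr, cc]
      if (type != "unmyelinated") {
        inside_out <- (u / a_out)^2 + (v / b_out)^2 <= 1
        block[inside_out & !inside_in] <- 2L
      }
      block[inside_in] <- 1L
      cls[rr, cc] <- block
      truth[[i]] <- data.frame(
        id = i, type = type, cx = cx, cy = cy,
        inner_diameter = 2 * b_in * pixel_size,
        outer_diameter = 2 * b_out * pixel_size,
        g = if (type == "unmyelinated") NA_real_ else g,
        eccentricity = sqrt(1 - 1 / aspect^2), phi = phi)
    }
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = integer(0), type = character(0), cx = numeric(0),
               cy = numeric(0), inner_diameter = numeric(0),
               outer_diameter = numeric(0), g = numeric(0),
               eccentricity = numeric(0), phi = numeric(0))
  list(mask = label_mask(cls, pixel_size = pixel_size,
                         preparation = preparation),
       truth = truth_df)
}

#' Deterministic quasi-uniform gradient directions
#'
#' Golden-angle (Fibonacci) spiral over the upper hemisphere — adequate
#' quadrature nodes for powder averaging of antipodally symmetric signals.
#'
#' @param n Number of directions.
#' @return n x 3 unit-vector matrix.
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n)
  z <- (i - 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Synthetic direction-resolved diffusion dataset from the cylinder model
#'
#' Builds a `dwi_dataset` whose voxels contain impermeable cylinders of known
#' diameter: for each direction the signal of an axially symmetric
#' compartment with apparent perpendicular diffusivity from the GPD cylinder
#' map, plus Rician noise. Ground truth per voxel is returned.
#'
#' @param n_voxels Number of voxels (stored as an n x 1 x 1 grid).
#' @param diameters Scalar, vector of length `n_voxels`, or `NULL` to draw
#'   from the diameter law of `target`.
#' @param target Diameter-law target when `diameters` is NULL.
#' @param va Intra-axonal signal fraction.
#' @param D0 Intrinsic diffusivity, \eqn{\mu m^2}/ms.
#' @param protocol A `pgse_protocol` (default [protocol_diameter()]).
#' @param snr Rician SNR; `Inf` for noiseless.
#' @param axis `"random"` per-voxel cylinder axis, or a fixed unit 3-vector.
#' @param seed Optional RNG seed.
#' @return List: `dataset` (a `dwi_dataset`) and `truth` (data.frame with
#'   per-voxel diameter, va, Dperp).
#' @export
gen_dmri_signals <- function(n_voxels, diameters = NULL, target = "epon",
                             va = 0.7, D0 = 0.6,
                             protocol = protocol_diameter(), snr = Inf,
                             axis = "random", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- if (is.null(diameters))
    gen_diameter_sample(n_voxels, target = target)$diameters
  else rep_len(diameters, n_voxels)
  dirs <- fibonacci_directions(protocol$n_directions)
  shells <- protocol$shells
  n_meas <- protocol$n_b0 + nrow(shells) * protocol$n_directions
  bvals <- c(rep(0, protocol$n_b0),
             rep(shells$b_nominal, each = protocol$n_directions))
  bvecs <- rbind(matrix(0, protocol$n_b0, 3),
                 dirs[rep(seq_len(protocol$n_directions), nrow(shells)), ])
  vol <- array(0, c(n_voxels, 1, 1, n_meas))
  dperp_true <- numeric(n_voxels)
  delta_ms <- protocol$delta * 1e3
  Delta_ms <- protocol$Delta * 1e3
  for (v in seq_len(n_voxels)) {
    u <- if (identical(axis, "random")) {
      x <- rnorm(3); x / sqrt(sum(x^2))
    } else axis / sqrt(sum(axis^2))
    dperp <- effective_Dperp(d[v] / 2, delta_ms, Delta_ms, D0,
                             gamma = protocol$gamma)
    dperp_true[v] <- dperp
    sig <- rep(1, protocol$n_b0)
    for (sh in seq_len(nrow(shells))) {
      b_ms <- shells$b_nominal[sh] * 1e-3
      cos2 <- (dirs %*% u)^2
      sig <- c(sig, va * exp(-b_ms * (dperp + (D0 - dperp) * cos2)))
    }
    if (is.finite(snr)) sig <- add_rician_noise(sig, snr)
    vol[v, 1, 1, ] <- sig
  }
  list(dataset = dwi_dataset(vol, bvals, bvecs),
       truth = data.frame(diameter = d, va = va, Dperp = dperp_true))
}

#' Synthetic multi-trial evoked LFP recording
#'
#' Each trial is a baseline drift plus a Gaussian-shaped positive deflection
#' (P1) and negative deflection (N1) at the requested latencies, recorded on
#' two channels with a small gain mismatch and white trial noise.
#'
#' @param n_trials Number of trials.
#' @param n_channels Number of channels (default 2, a stereotrode pair).
#' @param fs Sampling rate, Hz.
#' @param pre_ms,post_ms Record length before/after the stimulus, ms.
#' @param p1_ms,n1_ms Deflection latencies, ms (defaults 5.6 and 11.8, the
#'   cohort group means).
#' @param p1_amp,n1_amp Deflection amplitudes, \eqn{\mu V}.
#' @param p1_width_ms,n1_width_ms Gaussian widths (SD), ms.
#' @param noise_sd White-noise SD per sample, \eqn{\mu V}.
#' @param drift_amp Per-trial baseline offset SD, \eqn{\mu V}.
#' @param gain_mismatch Relative channel gain SD.
#' @param seed Optional RNG seed.
#' @return List: `trace` (an `lfp_trace`) and `truth` (p1/n1 latencies, ms).
#' @export
gen_lfp <- function(n_trials = 100, n_channels = 2, fs = 30000,
                    pre_ms = 60, post_ms = 30,
                    p1_ms = 5.6, n1_ms = 11.8,
                    p1_amp = 15, n1_amp = -40,
                    p1_width_ms = 0.8, n1_width_ms = 2.0,
                    noise_sd = 5, drift_amp = 2, gain_mismatch = 0.05,
                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (p1_ms <= 1 || p1_ms >= 9 || n1_ms <= 5 || n1_ms >= 20)
    warning("injected latencies fall outside the standard detection windows")
  n_pre <- round(pre_ms * fs / 1e3)
  n_post <- round(post_ms * fs / 1e3)
  n_samp <- n_pre + n_post + 1L
  stim <- n_pre + 1L
  t_ms <- ((seq_len(n_samp)) - stim) * 1e3 / fs
  template <- p1_amp * exp(-(t_ms - p1_ms)^2 / (2 * p1_width_ms^2)) +
    n1_amp * exp(-(t_ms - n1_ms)^2 / (2 * n1_width_ms^2))
  gains <- 1 + rnorm(n_channels, sd = gain_mismatch)
  data <- array(0, c(n_trials, n_channels, n_samp))
  for (tr in seq_len(n_trials)) {
    offset <- rnorm(1, sd = drift_amp)
    for (ch in seq_len(n_channels)) {
      data[tr, ch, ] <- gains[ch] * template + offset +
        rnorm(n_samp, sd = noise_sd)
    }
  }
  list(trace = lfp_trace(data, fs = fs, stim_index = stim),
       truth = list(p1_ms = p1_ms, n1_ms = n1_ms))
}
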