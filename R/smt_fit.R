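#' Powder-average a voxel's diffusion measurements
#'
#' Normalizes a voxel's signal vector by the mean of its b0 (unweighted)
#' measurements and takes the arithmetic mean across directions within each
#' shell.
#'
#' @param signals Signal vector, one value per measurement.
#' @param bvals b-value per measurement, s/mm\eqn{^2}.
#' @param b0_threshold b-values below this are unweighted.
#' @param shell_round Shells are grouped by `round(bvals / shell_round)`;
#'   default groups b-values within ~10 s/mm\eqn{^2}.
#' @return A `powder_signal`: `b_shells` (ascending), `sbar` (normalized
#'   spherical-mean signal per shell), `n_dirs`, `valid`. A voxel whose b0
#'   mean is not positive, or whose normalized signal exceeds 1.5, is marked
#'   invalid. Noise-floor values slightly above 1 are tolerated.
#' @export
powder_average <- function(signals, bvals, b0_threshold = B0_THRESHOLD,
                           shell_round = 10) {
  stopifnot(length(signals) == length(bvals))
  is_b0 <- bvals < b0_threshold
  if (!any(is_b0)) stop("powder_average needs at least one b0 measurement")
  s0 <- mean(signals[is_b0])
  if (!is.finite(s0) || s0 <= 0) {
    return(structure(list(b_shells = numeric(0), sbar = numeric(0),
                          n_dirs = integer(0), valid = FALSE),
                     class = "powder_signal"))
  }
  key <- round(bvals[!is_b0] / shell_round) * shell_round
  ord <- sort(unique(key))
  sbar <- vapply(ord, function(b) mean(signals[!is_b0][key == b] / s0),
                 numeric(1))
  nd <- vapply(ord, function(b) sum(key == b), integer(1))
  bsh <- vapply(ord, function(b) mean(bvals[!is_b0][key == b]), numeric(1))
  valid <- all(is.finite(sbar)) && all(sbar <= 1.5) && all(sbar >= 0)
  structure(list(b_shells = bsh, sbar = sbar, n_dirs = nd, valid = valid),
            class = "powder_signal")
}

#' Principal diffusivity from a log-linear tensor fit
#'
#' Fits the diffusion-tensor model by linear least squares on log-signals and
#' returns the largest eigenvalue — the diffusivity along the principal fiber
#' direction, used as the fixed intrinsic diffusivity \eqn{D_0}. If `signals`
#' is a matrix (voxels x measurements), each voxel is fitted and the largest
#' eigenvalues are averaged over voxels.
#'
#' @param signals Vector (one voxel) or matrix (voxels x measurements).
#' @param bvecs N x 3 unit direction matrix.
#' @param bvals b-values, s/mm\eqn{^2}.
#' @param b0_threshold Unweighted-image threshold.
#' @return \eqn{D_0} in \eqn{\mu m^2}/ms.
#' @export
fit_dti_principal_diffusivity <- function(signals, bvecs, bvals,
                                          b0_threshold = B0_THRESHOLD) {
  if (is.matrix(signals)) {
    lams <- apply(signals, 1, fit_dti_principal_diffusivity,
                  bvecs = bvecs, bvals = bvals, b0_threshold = b0_threshold)
    return(mean(lams))
  }
  stopifnot(length(signals) == length(bvals), nrow(bvecs) == length(bvals))
  dw <- bvals >= b0_threshold
  dirs <- unique(round(bvecs[dw, , drop = FALSE], 6))
  ## antipodal directions measure the same tensor projection
  dirs <- unique(rbind(dirs, -dirs))
  if (nrow(dirs) / 2 < 6)
    stop("fit error: need at least 6 unique gradient directions")
  bm <- bvals * 1e-3 # ms/um^2 so the tensor comes out in um^2/ms
  g <- bvecs
  X <- cbind(1, -bm * g[, 1]^2, -bm * g[, 2]^2, -bm * g[, 3]^2,
             -2 * bm * g[, 1] * g[, 2], -2 * bm * g[, 1] * g[, 3],
             -2 * bm * g[, 2] * g[, 3])
  if (any(signals <= 0)) stop("fit error: non-positive signal")
  beta <- tryCatch(solve(crossprod(X), crossprod(X, log(signals))),
                   error = function(e) stop("fit error: rank-deficient design"))
  Dmat <- matrix(c(beta[2], beta[5], beta[6],
                   beta[5], beta[3], beta[7],
                   beta[6], beta[7], beta[4]), 3, 3)
  max(eigen(Dmat, symmetric = TRUE, only.values = TRUE)$values)
}

#' Fit the powder-average cylinder model to spherical-mean signals
#'
#' Bounded non-linear least squares for the intra-axonal signal fraction
#' \eqn{v_a \in [0, 1]} and apparent perpendicular diffusivity
#' \eqn{D_\perp \in [0, D_0]}, with the intrinsic diffusivity \eqn{D_0} held
#' fixed. The objective has a shallow valley at low \eqn{D_\perp}, so the
#' best of several starts on a \eqn{(v_a, D_\perp)} grid is kept.
#'
#' @param powder A `powder_signal` (or list with `b_shells`, `sbar`).
#' @param D0 Fixed intrinsic diffusivity, \eqn{\mu m^2}/ms.
#' @param n_starts Number of multi-start initializations (default 5).
#' @param va_fixed Optionally hold the signal fraction at a known value and
#'   fit \eqn{D_\perp} alone (used when simulating single cylinders, where
#'   \eqn{v_a = 1} by construction).
#' @return An `smt_fit` list: `va`, `Dperp` (\eqn{\mu m^2}/ms), `D0_used`,
#'   `residual_norm`, `converged`.
#' @export
fit_smt <- function(powder, D0, n_starts = 5, va_fixed = NULL) {
  if (D0 <= 0) stop("invalid parameter: D0 must be positive")
  b <- powder$b_shells
  y <- powder$sbar
  if (length(b) < 2) stop("fit error: need at least 2 shells")
  if (!is.null(va_fixed)) {
    opt <- optimize(function(dp)
      sum((smt_powder_signal(b, va_fixed, D0, dp) - y)^2),
      interval = c(0, D0), tol = 1e-12)
    return(structure(list(va = va_fixed, Dperp = opt$minimum, D0_used = D0,
                          residual_norm = sqrt(opt$objective),
                          converged = TRUE),
                     class = "smt_fit"))
  }
  obj <- function(p) {
    pred <- smt_powder_signal(b, p[1], D0, p[2])
    sum((pred - y)^2)
  }
  starts <- cbind(va    = c(0.3, 0.6, 0.9, 0.6, 0.9),
                  Dperp = c(0.05, 0.05, 0.05, 0.4, 0.8) * D0)
  starts <- starts[seq_len(min(n_starts, nrow(starts))), , drop = FALSE]
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], obj, method = "L-BFGS-B",
            lower = c(0, 0), upper = c(1, D0),
            control = list(factr = 10, maxit = 500,
                           parscale = c(0.1, 0.02 * D0))),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_conv <- any_conv || fit$convergence == 0
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(structure(list(va = NA_real_, Dperp = NA_real_, D0_used = D0,
                          residual_norm = NA_real_, converged = FALSE),
                     class = "smt_fit"))
  structure(list(va = unname(best$par[1]), Dperp = unname(best$par[2]),
                 D0_used = D0, residual_norm = sqrt(best$value),
                 converged = any_conv),
            class = "smt_fit")
}

#' Invert apparent perpendicular diffusivity to cylinder diameter
#'
#' Solves `effective_Dperp(R) = Dperp` for the radius by bisection on the
#' monotone forward map (shared \eqn{\delta, \Delta}; gradient-strength
#' independent) and returns the diameter d = 2R. `Dperp = 0` maps to d = 0;
#' values above the forward map's range over R in \[0, 10\] \eqn{\mu m} are
#' capped at d = 20 \eqn{\mu m} and flagged in the `"capped"` attribute.
#'
#' @param Dperp Apparent perpendicular diffusivity(ies), \eqn{\mu m^2}/ms.
#' @param delta_ms,Delta_ms Pulse timings, ms.
#' @param D0 Intrinsic diffusivity, \eqn{\mu m^2}/ms.
#' @param gamma Gyromagnetic ratio, rad/s/T.
#' @return Diameter(s) in \eqn{\mu m}, with logical attribute `"capped"`.
#' @export
diameter_from_Dperp <- function(Dperp, delta_ms, Delta_ms, D0,
                                gamma = GAMMA_PROTON) {
  if (any(Dperp < 0)) stop("invalid parameter: negative Dperp")
  if (any(Dperp > D0)) stop("invalid parameter: Dperp exceeds D0")
  r_max <- 10
  d_top <- effective_Dperp(r_max, delta_ms, Delta_ms, D0, gamma = gamma)
  d <- numeric(length(Dperp))
  capped <- logical(length(Dperp))
  for (i in seq_along(Dperp)) {
    dp <- Dperp[i]
    if (dp == 0) { d[i] <- 0; next }
    if (dp >= d_top) { d[i] <- 2 * r_max; capped[i] <- TRUE; next }
    r <- uniroot(function(r) effective_Dperp(r, delta_ms, Delta_ms, D0,
                                             gamma = gamma) - dp,
                 lower = 1e-4, upper = r_max, tol = 1e-9)$root
    d[i] <- 2 * r
  }
  attr(d, "capped") <- capped
  d
}

#' Fit a diameter map over an ROI of a diffusion dataset
#'
#' Runs [powder_average()], [fit_smt()] and [diameter_from_Dperp()] for every
#' ROI voxel of a `dwi_dataset`.
#'
#' @param dataset A `dwi_dataset`.
#' @param roi Logical 3D array, same spatial dimensions as the volume;
#'   `NULL` means all voxels.
#' @param protocol A `pgse_protocol` supplying \eqn{\delta, \Delta, \gamma}.
#' @param D0 Fixed intrinsic diffusivity, \eqn{\mu m^2}/ms.
#' @return A `diameter_map`: `diameter` (3D array, NA outside ROI/invalid),
#'   `state` (3D character: `outside`, `invalid`, `zero`, `ok`), `roi`.
#' @export
fit_diameter_map <- function(dataset, roi = NULL, protocol, D0) {
  dims <- dim(dataset$volume)[1:3]
  if (is.null(roi)) roi <- array(TRUE, dims)
  stopifnot(all(dim(roi) == dims))
  diam <- array(NA_real_, dims)
  state <- array("outside", dims)
  idx <- which(roi, arr.ind = TRUE)
  for (v in seq_len(nrow(idx))) {
    i <- idx[v, 1]; j <- idx[v, 2]; k <- idx[v, 3]
    pw <- powder_average(dataset$volume[i, j, k, ], dataset$bvals)
    if (!pw$valid) { state[i, j, k] <- "invalid"; next }
    fit <- fit_smt(pw, D0 = D0)
    if (!fit$converged || is.na(fit$Dperp)) { state[i, j, k] <- "invalid"; next }
    d <- diameter_from_Dperp(fit$Dperp, protocol$delta * 1e3,
                             protocol$Delta * 1e3, D0,
                             gamma = protocol$gamma)
    diam[i, j, k] <- as.numeric(d)
    state[i, j, k] <- if (d == 0) "zero" else "ok"
  }
  structure(list(diameter = diam, state = state, roi = roi),
            class = "diameter_map")
}

#' Diameter-distribution summary over an ROI
#'
#' Summarizes an ROI's voxel-wise diameter estimates, excluding zero-diameter
#' voxels (perpendicular diffusivity at its lower bound) and sub-resolution
#' estimates below the discard limit, both of which are counted separately.
#'
#' @param x A `diameter_map` or a numeric vector of voxel diameters.
#' @param discard_below Diameters in (0, `discard_below`) are discarded
#'   (default 0.1 \eqn{\mu m}).
#' @return A list: `stats` ([distribution_stats()] over retained voxels),
#'   `n_zero`, `n_discarded`, `n_used`, `frac_excluded`.
#' @export
roi_diameter_distribution <- function(x, discard_below = 0.1) {
  d <- if (inherits(x, "diameter_map")) x$diameter[x$roi] else x
  d <- d[!is.na(d)]
  if (!length(d)) stop("empty distribution: no valid voxels in ROI")
  zero <- d == 0
  disc <- d > 0 & d < discard_below
  keep <- d >= discard_below
  if (!any(keep)) stop("empty distribution: all voxels zero or discarded")
  list(stats = distribution_stats(d[keep]),
       n_zero = sum(zero), n_discarded = sum(disc), n_used = sum(keep),
       frac_excluded = (sum(zero) + sum(disc)) / length(d))
}
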