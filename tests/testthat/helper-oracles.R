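# Independent numerical oracles, coded separately from the package's
# closed-form implementations so agreement is evidence, not tautology.

# Perpendicular cylinder attenuation by fine quadrature of the phase-variance
# double time-integral, -ln S = (gamma^2/2) int int g(t1) g(t2) <x(t1)x(t2)>,
# using the disk position-autocorrelation eigenexpansion. Bessel-derivative
# roots are located here by uniroot, independently of the package cache.
gpd_signal_oracle <- function(R_um, G_mT_m, delta_ms, Delta_ms, D0,
                              n_roots = 60, n_quad = 500) {
  G <- G_mT_m / 1e3; delta <- delta_ms / 1e3; Delta <- Delta_ms / 1e3
  D <- D0 * 1e-9; R <- R_um * 1e-6; gam <- 2.6752218744e8
  f <- function(x) besselJ(x, 0) - besselJ(x, 1) / x
  roots <- numeric(n_roots); lo <- 1
  for (m in seq_len(n_roots)) {
    hi <- lo + 2.5
    while (f(lo) * f(hi) > 0) hi <- hi + 0.5
    roots[m] <- uniroot(f, c(lo, hi), tol = 1e-14)$root
    lo <- roots[m] + 2.5
  }
  amp <- 2 * R^2 / (roots^2 * (roots^2 - 1)) # <x(0)x(0)> partition: sums to R^2/4
  lam <- D * roots^2 / R^2
  K <- function(tau) colSums(amp * exp(-outer(lam, tau)))
  x <- seq(0, 1, length.out = n_quad)
  w <- rep(1, n_quad); w[c(1, n_quad)] <- 0.5; w <- w / (n_quad - 1)
  segs <- list(x * delta, Delta + x * delta) # +G lobe, -G lobe
  tot <- 0
  for (i in 1:2) for (j in 1:2) {
    sgn <- if (i == j) 1 else -1
    TT <- abs(outer(segs[[i]], segs[[j]], "-"))
    Kv <- matrix(K(as.vector(TT)), n_quad, n_quad)
    tot <- tot + sgn * as.numeric(t(w) %*% Kv %*% w) * delta^2
  }
  exp(-gam^2 * G^2 * tot / 2)
}

# powder_signal constructor for synthetic per-shell values
make_powder <- function(b, sbar, n_dirs = 30) {
  structure(list(b_shells = b, sbar = sbar,
                 n_dirs = rep(n_dirs, length(b)), valid = TRUE),
            class = "powder_signal")
}

# fit + invert a dwi_dataset voxel to a diameter (convenience for tests)
voxel_diameter <- function(gen, v, D0 = 0.6) {
  pw <- powder_average(gen$dataset$volume[v, 1, 1, ], gen$dataset$bvals)
  fit <- fit_smt(pw, D0 = D0)
  as.numeric(diameter_from_Dperp(fit$Dperp, 8, 18, D0))
}
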