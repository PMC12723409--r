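## Cache for roots of J1'(x) = 0 (derivative of the first-order Bessel
## function), the eigenvalue ladder of the GPD cylinder series.
.axonsf_cache <- new.env(parent = emptyenv())

#' Roots of the derivative of the first-order Bessel function
#'
#' Returns the first `n` positive roots of \eqn{J_1'(x) = 0}, computed once by
#' bisection on \eqn{J_0(x) - J_1(x)/x} and cached. These are the radial
#' eigenvalues of diffusion restricted in a cylinder cross-section.
#'
#' @param n Number of roots.
#' @return Numeric vector of length `n` (first root 1.8412...).
#' @export
bessel_j1prime_roots <- function(n = 20) {
  cached <- .axonsf_cache$j1p_roots
  if (!is.null(cached) && length(cached) >= n) return(cached[seq_len(n)])
  f <- function(x) besselJ(x, 0) - besselJ(x, 1) / x
  roots <- numeric(n)
  lo <- 1e-3
  for (m in seq_len(n)) {
    hi <- lo + 0.5
    while (f(lo) * f(hi) > 0) hi <- hi + 0.5
    roots[m] <- uniroot(f, c(lo, hi), tol = 1e-14)$root
    lo <- roots[m] + 2 # next root is ~pi away
  }
  .axonsf_cache$j1p_roots <- roots
  roots
}

#' Perpendicular PGSE signal of a cylinder (Gaussian phase distribution)
#'
#' Attenuation of spins diffusing inside an impermeable cylinder of radius `R`
#' when the gradient is applied perpendicular to its axis, under the Gaussian
#' phase distribution (GPD) approximation for rectangular PGSE pulses
#' (Van Gelderen series over the roots of \eqn{J_1'}).
#'
#' @param R_um Cylinder radius, micrometres (vectorized).
#' @param G_mT_m Gradient strength, mT/m.
#' @param delta_ms Gradient duration, ms.
#' @param Delta_ms Gradient separation, ms.
#' @param D0 Intrinsic diffusivity, \eqn{\mu m^2}/ms.
#' @param gamma Gyromagnetic ratio, rad/s/T.
#' @param n_roots Number of Bessel-root terms (default 20; the tail beyond
#'   this changes the signal by far less than 1e-8 at protocol-scale
#'   parameters).
#' @return Signal fraction \eqn{S_\perp \in (0, 1]}; exactly 1 at R = 0 or
#'   G = 0.
#' @export
gpd_perpendicular_signal <- function(R_um, G_mT_m, delta_ms, Delta_ms, D0,
                                     gamma = GAMMA_PROTON, n_roots = 20) {
  if (D0 <= 0) stop("invalid parameter: D0 must be positive")
  if (any(R_um < 0)) stop("invalid parameter: negative radius")
  if (delta_ms <= 0 || Delta_ms < delta_ms)
    stop("invalid protocol: need delta > 0 and Delta >= delta")
  G <- G_mT_m / 1e3          # T/m
  delta <- delta_ms / 1e3    # s
  Delta <- Delta_ms / 1e3    # s
  D <- D0 * 1e-9             # um^2/ms -> m^2/s
  R <- R_um * 1e-6           # m
  beta <- bessel_j1prime_roots(n_roots)
  out <- vapply(R, function(r) {
    if (r == 0 || G == 0) return(1)
    a2 <- D * beta^2 / r^2   # decay rates, 1/s
    num <- 2 * a2 * delta - 2 +
      2 * exp(-a2 * delta) + 2 * exp(-a2 * Delta) -
      exp(-a2 * (Delta - delta)) - exp(-a2 * (Delta + delta))
    ## alpha^6 (alpha^2 R^2 - 1) with alpha = beta / r
    den <- (beta / r)^6 * (beta^2 - 1) * D^2
    exp(-2 * gamma^2 * G^2 * sum(num / den))
  }, numeric(1))
  out
}

#' Apparent perpendicular diffusivity of a cylinder
#'
#' Maps the GPD perpendicular attenuation into an apparent diffusivity,
#' \eqn{D_\perp = -\ln S_\perp / b}. Because both the GPD log-attenuation and
#' b scale with \eqn{G^2}, the result is identical for all shells sharing
#' \eqn{(\delta, \Delta)} — the gradient strength cancels exactly.
#'
#' @inheritParams gpd_perpendicular_signal
#' @param G_mT_m Reference gradient strength used for the evaluation; the
#'   result does not depend on it (any positive value gives the same
#'   \eqn{D_\perp}).
#' @return \eqn{D_\perp} in \eqn{\mu m^2}/ms; 0 at R = 0.
#' @export
effective_Dperp <- function(R_um, delta_ms, Delta_ms, D0,
                            gamma = GAMMA_PROTON, G_mT_m = 590,
                            n_roots = 20) {
  s <- gpd_perpendicular_signal(R_um, G_mT_m, delta_ms, Delta_ms, D0,
                                gamma = gamma, n_roots = n_roots)
  b <- compute_bvalue(G_mT_m / 1e3, delta_ms / 1e3, Delta_ms / 1e3, gamma)
  b_ms_um2 <- b * 1e-3 # s/mm^2 -> ms/um^2
  dperp <- -log(s) / b_ms_um2
  dperp[R_um == 0] <- 0
  dperp
}

#' Spherical-mean (powder-average) signal of an axially symmetric compartment
#'
#' Closed-form arithmetic mean over uniformly distributed gradient directions
#' of \eqn{v_a \exp(-b (D_\perp + (D_\parallel - D_\perp)\cos^2\theta))}:
#' \deqn{\bar S = v_a e^{-b D_\perp}
#'   \sqrt{\pi / (4 b (D_\parallel - D_\perp))}\,
#'   \mathrm{erf}(\sqrt{b (D_\parallel - D_\perp)}).}
#' A 3-term Taylor expansion replaces the erf form when
#' \eqn{b(D_\parallel - D_\perp) < 10^{-6}} so the isotropic limit is
#' continuous.
#'
#' @param b b-value(s), s/mm\eqn{^2} (vectorized).
#' @param va Intra-axonal signal fraction in \[0, 1\].
#' @param Dpar Parallel (axial) diffusivity, \eqn{\mu m^2}/ms.
#' @param Dperp Perpendicular diffusivity, \eqn{\mu m^2}/ms; must not exceed
#'   `Dpar`.
#' @return Normalized powder-average signal in \[0, `va`\].
#' @export
smt_powder_signal <- function(b, va, Dpar, Dperp) {
  if (any(b < 0)) stop("invalid parameter: negative b")
  if (va < 0 || va > 1) stop("invalid parameter: va outside [0, 1]")
  if (Dperp < 0 || Dperp > Dpar)
    stop("invalid parameter: need 0 <= Dperp <= Dpar")
  bm <- b * 1e-3 # ms/um^2
  x <- bm * (Dpar - Dperp)
  ## sqrt(pi/(4x)) erf(sqrt(x)), with series 1 - x/3 + x^2/10 near x = 0
  f <- ifelse(x < 1e-6,
              1 - x / 3 + x^2 / 10,
              sqrt(pi / (4 * x)) * (2 * pnorm(sqrt(2 * x)) - 1))
  va * exp(-bm * Dperp) * f
}

#' Add Rician noise to a magnitude signal
#'
#' Returns \eqn{|s + n_{re} + i\, n_{im}|} with independent Gaussian real and
#' imaginary components of standard deviation 1/SNR — the noise law of
#' magnitude MR images. Uses R's global RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param signal Noiseless magnitude signal(s), as a fraction of the
#'   unattenuated signal.
#' @param snr Signal-to-noise ratio (> 0); `Inf` returns the input unchanged.
#' @return Noisy magnitude signal(s).
#' @export
add_rician_noise <- function(signal, snr) {
  if (!is.numeric(snr) || snr <= 0)
    stop("invalid parameter: SNR must be positive")
  if (is.infinite(snr)) return(signal)
  n <- length(signal)
  sqrt((signal + rnorm(n, sd = 1 / snr))^2 + rnorm(n, sd = 1 / snr)^2)
}
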