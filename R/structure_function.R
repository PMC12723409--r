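#' Dehydration shrinkage factors between preparations
#'
#' Shrinkage of conventionally dehydrated (Epon) tissue relative to
#' cryo-fixed tissue, evaluated on the distribution mode and 90th percentile:
#' \eqn{s_x = (cryo_x - epon_x) \cdot 100 / cryo_x}. The general factor is
#' the mean of the two — larger axons shrink more, so the two differ.
#'
#' @param epon,cryo `distribution_stats` (or lists with `mode`, `p90`).
#' @return A `shrinkage_result`: `s_mode`, `s_p90`, `s_general`, all percent.
#' @export
shrinkage_factor <- function(epon, cryo) {
  if (!is.finite(cryo$mode) || cryo$mode <= 0 ||
      !is.finite(cryo$p90) || cryo$p90 <= 0)
    stop("cryo reference mode and p90 must be positive")
  s_mode <- (cryo$mode - epon$mode) * 100 / cryo$mode
  s_p90 <- (cryo$p90 - epon$p90) * 100 / cryo$p90
  structure(list(s_mode = s_mode, s_p90 = s_p90,
                 s_general = (s_mode + s_p90) / 2),
            class = "shrinkage_result")
}

#' @export
print.shrinkage_result <- function(x, ...) {
  cat(sprintf("shrinkage: mode %.1f%%, p90 %.1f%%, general %.1f%%\n",
              x$s_mode, x$s_p90, x$s_general))
  invisible(x)
}

#' Correct measured diameters for tissue shrinkage
#'
#' The exact inverse of the shrinkage definition: a diameter measured after
#' shrinking by `s` percent of the reference value is restored by dividing by
#' (1 - s/100). A multiplicative alternative (times 1 + s/100) is available
#' behind `method = "multiplicative"` for comparison with conventions that
#' define shrinkage relative to the shrunken value.
#'
#' @param diameters Measured diameters, \eqn{\mu m}.
#' @param s Shrinkage percentage in \[0, 100).
#' @param method `"divide"` (default, exact inverse) or `"multiplicative"`.
#' @return Corrected diameters, \eqn{\mu m}.
#' @export
apply_shrinkage_correction <- function(diameters, s, method = c("divide", "multiplicative")) {
  method <- match.arg(method)
  if (s < 0 || s >= 100) stop("shrinkage percentage must be in [0, 100)")
  if (method == "divide") diameters / (1 - s / 100)
  else diameters * (1 + s / 100)
}

#' MR-weighted effective diameter
#'
#' The tail-weighted diameter an MRI voxel reports in the wide-pulse limit,
#' \eqn{d_w = 2 (\langle R^6 \rangle / \langle R^2 \rangle)^{1/4}} with
#' R = d/2. Always at least the arithmetic mean, with equality only for a
#' monodisperse sample.
#'
#' @param diameters Positive diameters, \eqn{\mu m}.
#' @return \eqn{d_w}, \eqn{\mu m}.
#' @export
mr_weighted_diameter <- function(diameters) {
  if (!length(diameters)) stop("empty input")
  if (any(diameters <= 0)) stop("diameters must be positive")
  R <- diameters / 2
  2 * (mean(R^6) / mean(R^2))^0.25
}

#' Conduction velocity from pathway length and conduction time
#'
#' CV = L / TCT; with L in mm and TCT in ms the result is in m/s.
#'
#' @param L Pathway length, mm.
#' @param TCT Conduction time, ms.
#' @return Conduction velocity, m/s.
#' @export
conduction_velocity <- function(L, TCT) {
  if (any(L <= 0) || any(TCT <= 0)) stop("L and TCT must be positive")
  L / TCT
}

#' Conduction velocity from axon diameter and g-ratio
#'
#' The linear structure-function relation for myelinated CNS axons:
#' CV = 5.5 m/s per \eqn{\mu m} of outer diameter, i.e. (5.5 / g) d for
#' inner diameter d.
#'
#' @param d Inner axon diameter, \eqn{\mu m}.
#' @param g g-ratio (inner / outer diameter), in (0, 1).
#' @param k Proportionality constant, m/s per \eqn{\mu m} outer diameter
#'   (default 5.5).
#' @return Conduction velocity, m/s.
#' @export
cv_from_diameter <- function(d, g, k = 5.5) {
  if (any(d <= 0)) stop("diameter must be positive")
  if (any(g <= 0) || any(g >= 1)) stop("g-ratio must be in (0, 1)")
  (k / g) * d
}

#' Predict axon diameter from a measured conduction time
#'
#' Combines CV = L/TCT with CV = (5.5/g) d into d = L g / (5.5 TCT).
#'
#' @param TCT Conduction time, ms.
#' @param L Pathway length, mm.
#' @param g g-ratio in (0, 1).
#' @param k Proportionality constant (default 5.5).
#' @return Inner axon diameter, \eqn{\mu m}.
#' @export
predict_diameter <- function(TCT, L, g, k = 5.5) {
  if (any(TCT <= 0) || any(L <= 0)) stop("TCT and L must be positive")
  if (any(g <= 0) || any(g >= 1)) stop("g-ratio must be in (0, 1)")
  L * g / (k * TCT)
}

#' Predict conduction time from axon diameter
#'
#' The inverse of [predict_diameter()]: TCT = L g / (5.5 d).
#'
#' @param d Inner axon diameter, \eqn{\mu m}.
#' @param L Pathway length, mm.
#' @param g g-ratio in (0, 1).
#' @param k Proportionality constant (default 5.5).
#' @return Conduction time, ms.
#' @export
predict_tct <- function(d, L, g, k = 5.5) {
  if (any(d <= 0) || any(L <= 0)) stop("d and L must be positive")
  if (any(g <= 0) || any(g >= 1)) stop("g-ratio must be in (0, 1)")
  L * g / (k * d)
}

#' Consistent pathway structure-function state
#'
#' Holds (L, TCT, CV, g, d) and verifies the two defining relations
#' CV = L/TCT and CV = (5.5/g) d whenever all fields are populated. Missing
#' fields are completed from the others when possible.
#'
#' @param L Pathway length, mm.
#' @param TCT Conduction time, ms.
#' @param CV Conduction velocity, m/s.
#' @param g g-ratio.
#' @param d Inner axon diameter, \eqn{\mu m}.
#' @param k Proportionality constant (default 5.5).
#' @return A `pathway_model` list.
#' @export
pathway_model <- function(L = NA, TCT = NA, CV = NA, g = NA, d = NA, k = 5.5) {
  if (is.na(CV) && !is.na(L) && !is.na(TCT)) CV <- conduction_velocity(L, TCT)
  if (is.na(CV) && !is.na(d) && !is.na(g)) CV <- cv_from_diameter(d, g, k)
  if (is.na(TCT) && !is.na(L) && !is.na(CV)) TCT <- L / CV
  if (is.na(d) && !is.na(CV) && !is.na(g)) d <- CV * g / k
  rel_ok <- function(a, b) abs(a - b) <= 1e-6 * max(abs(a), abs(b))
  if (!is.na(L) && !is.na(TCT) && !is.na(CV) && !rel_ok(CV * TCT, L))
    stop("inconsistent pathway_model: CV * TCT != L")
  if (!is.na(CV) && !is.na(g) && !is.na(d) && !rel_ok(CV, k / g * d))
    stop("inconsistent pathway_model: CV != (k/g) d")
  structure(list(L = L, TCT = TCT, CV = CV, g = g, d = d, k = k),
            class = "pathway_model")
}
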