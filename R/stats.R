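#' Mode of a distribution by kernel density estimation
#'
#' Gaussian-kernel KDE with Silverman's rule-of-thumb bandwidth by default,
#' evaluated on a 512-point grid over \[max(0, min - 3h), max + 3h\]; the mode
#' is the grid argmax. A single value (or a constant sample) is its own mode.
#'
#' @param values Numeric sample (diameters are non-negative, so the grid is
#'   floored at 0).
#' @param bandwidth Bandwidth rule or numeric value, as `bw` in
#'   [stats::density()] (default `"nrd0"`, Silverman).
#' @param n_grid Grid resolution (default 512).
#' @return The mode, same units as `values`.
#' @export
kde_mode <- function(values, bandwidth = "nrd0", n_grid = 512) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty input")
  if (length(unique(values)) == 1) return(values[1])
  h <- if (is.numeric(bandwidth)) bandwidth else bw.nrd0(values)
  dens <- density(values, bw = h, n = n_grid,
                  from = max(0, min(values) - 3 * h),
                  to = max(values) + 3 * h)
  dens$x[which.max(dens$y)]
}

#' Summary statistics of a diameter distribution
#'
#' Mean, sample SD, KDE mode, 90th percentile (linear-interpolation
#' quantile) and optionally the tail-weighted MR-effective diameter.
#'
#' @param diameters Numeric sample, \eqn{\mu m}.
#' @param weighted Also compute [mr_weighted_diameter()] (requires all
#'   values positive).
#' @param bandwidth KDE bandwidth passed to [kde_mode()].
#' @return A `distribution_stats` list: `n`, `mean`, `sd`, `mode`, `p90`,
#'   and `d_w` (NA unless `weighted = TRUE`).
#' @export
distribution_stats <- function(diameters, weighted = FALSE,
                               bandwidth = "nrd0") {
  diameters <- diameters[!is.na(diameters)]
  if (!length(diameters)) stop("empty input")
  structure(list(
    n = length(diameters),
    mean = mean(diameters),
    sd = if (length(diameters) > 1) sd(diameters) else 0,
    mode = kde_mode(diameters, bandwidth = bandwidth),
    p90 = unname(quantile(diameters, 0.9, type = 7)),
    d_w = if (weighted) mr_weighted_diameter(diameters) else NA_real_
  ), class = "distribution_stats")
}

#' @export
print.distribution_stats <- function(x, ...) {
  cat(sprintf("n = %d: mean %.3f, sd %.3f, mode %.3f, p90 %.3f%s\n",
              x$n, x$mean, x$sd, x$mode, x$p90,
              if (is.na(x$d_w)) "" else sprintf(", d_w %.3f", x$d_w)))
  invisible(x)
}
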