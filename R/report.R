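#' Joint structure-function study report
#'
#' Orchestrates the full analysis over whichever modalities are supplied:
#' TEM morphometry of the two preparations (with shrinkage factors, the
#' shrinkage-corrected distributions and tail-weighted diameters), dMRI
#' voxel-wise diameter estimates, and evoked-potential conduction times.
#' Every diameter summary is paired with a predicted conduction time through
#' the linear conduction-velocity relation, and every measured conduction
#' time with a predicted diameter. Missing modalities are reported as absent,
#' not failed.
#'
#' @param epon,cryo Diameter samples from the two TEM preparations: a numeric
#'   vector of inner diameters (\eqn{\mu m}), a `label_mask`, or a
#'   `morphometry_result`.
#' @param dmri dMRI voxel diameters: numeric vector or a `diameter_map`.
#' @param lfp An `lfp_trace` (or list of traces); P1 latencies become the
#'   measured conduction times.
#' @param L Pathway length, mm (default 11.47, the tractography group mean).
#' @param g g-ratio for the conversions (default 0.64, the TEM group mean).
#' @param discard_below dMRI sub-resolution discard limit, \eqn{\mu m}.
#' @param smooth_ms,peak_window_ms Peak-detection settings passed to
#'   [detect_peaks()]; the report defaults (0.5 ms smoothing, 1 ms dominance
#'   window) are the robust settings for noisy multi-trial averages.
#' @param config Optional `run_config` recorded as provenance.
#' @return A `study_report` list: `modalities` (distribution stats with d_w),
#'   `shrinkage`, `predicted_tct` (per modality, for mean/mode/p90/d_w),
#'   `tct` (measured latencies, their predicted diameters), `dmri_exclusions`,
#'   `params`, `provenance`.
#' @export
run_report <- function(epon = NULL, cryo = NULL, dmri = NULL, lfp = NULL,
                       L = 11.47, g = 0.64, discard_below = 0.1,
                       smooth_ms = 0.5, peak_window_ms = 1,
                       config = NULL) {
  if (is.null(epon) && is.null(cryo) && is.null(dmri) && is.null(lfp))
    stop("usage error: no modality inputs supplied")
  as_diameters <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "label_mask")) x <- analyze_mask(x)
    if (inherits(x, "morphometry_result")) return(x$records$inner_diameter)
    as.numeric(x)
  }
  d_epon <- as_diameters(epon)
  d_cryo <- as_diameters(cryo)
  modal <- list()
  shrink <- NULL
  if (!is.null(d_epon)) modal$epon <- distribution_stats(d_epon, weighted = TRUE)
  if (!is.null(d_cryo)) modal$cryo <- distribution_stats(d_cryo, weighted = TRUE)
  if (!is.null(d_epon) && !is.null(d_cryo)) {
    shrink <- shrinkage_factor(modal$epon, modal$cryo)
    modal$epon_corrected <- distribution_stats(
      apply_shrinkage_correction(d_epon, shrink$s_general), weighted = TRUE)
  }
  dmri_excl <- NULL
  if (!is.null(dmri)) {
    rd <- roi_diameter_distribution(dmri, discard_below = discard_below)
    d_used <- if (inherits(dmri, "diameter_map")) {
      dd <- dmri$diameter[dmri$roi]; dd[!is.na(dd) & dd >= discard_below]
    } else dmri[!is.na(dmri) & dmri >= discard_below]
    modal$dmri <- distribution_stats(d_used, weighted = TRUE)
    dmri_excl <- rd[c("n_zero", "n_discarded", "n_used", "frac_excluded")]
  }
  predicted_tct <- lapply(modal, function(st) {
    vals <- c(mean = st$mean, mode = st$mode, p90 = st$p90, d_w = st$d_w)
    vals <- vals[!is.na(vals) & vals > 0]
    sapply(vals, predict_tct, L = L, g = g)
  })
  tct <- NULL
  if (!is.null(lfp)) {
    traces <- if (inherits(lfp, "lfp_trace")) list(lfp) else lfp
    lat <- vapply(traces, function(tr) {
      avg <- average_and_baseline(tr)
      pk <- detect_peaks(avg, tr$fs, tr$stim_index, smooth_ms = smooth_ms,
                         peak_window_ms = peak_window_ms)
      if (pk$has_p1) pk$p1_latency else NA_real_
    }, numeric(1))
    lat_ok <- lat[!is.na(lat)]
    tct <- list(p1_latencies_ms = lat,
                n_no_p1 = sum(is.na(lat)),
                predicted_diameter = if (length(lat_ok))
                  predict_diameter(lat_ok, L = L, g = g) else numeric(0))
  }
  structure(list(
    modalities = modal,
    shrinkage = shrink,
    predicted_tct = predicted_tct,
    tct = tct,
    dmri_exclusions = dmri_excl,
    params = list(L = L, g = g, discard_below = discard_below),
    provenance = list(
      seed = if (!is.null(config)) config$seed else NA_integer_,
      package_version = as.character(utils::packageVersion("axonsf")))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report (L =", x$params$L, "mm, g =", x$params$g, ")\n")
  for (nm in names(x$modalities)) {
    cat(sprintf("  %-14s ", nm)); print(x$modalities[[nm]])
  }
  if (!is.null(x$shrinkage)) { cat("  "); print(x$shrinkage) }
  if (!is.null(x$tct))
    cat(sprintf("  TCT: %d trace(s), median P1 %.2f ms -> d %.3f um\n",
                length(x$tct$p1_latencies_ms),
                median(x$tct$p1_latencies_ms, na.rm = TRUE),
                median(x$tct$predicted_diameter)))
  invisible(x)
}

#' Write a study report to JSON and CSV
#'
#' The JSON serialization contains no timestamps, so regenerating a report
#' from the same inputs and seed is byte-identical.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  rows <- do.call(rbind, lapply(names(report$modalities), function(nm) {
    st <- report$modalities[[nm]]
    data.frame(modality = nm, n = st$n, mean = st$mean, sd = st$sd,
               mode = st$mode, p90 = st$p90, d_w = st$d_w)
  }))
  csv_path <- file.path(dir, "summaries.csv")
  write.csv(rows, csv_path, row.names = FALSE)
  invisible(c(json_path, csv_path))
}

#' Extrapolate the diameter range implied by a conduction-time range
#'
#' Applies d = L g / (5.5 TCT) across a conduction-time range and a pathway
#' length range, pairing the longest conduction time with the shortest
#' pathway (minimum diameter) and the shortest conduction time with the
#' longest pathway (maximum diameter) so the returned interval spans all
#' combinations.
#'
#' @param tct_range Conduction-time range, ms (increasing).
#' @param length_range Pathway-length range, mm (increasing).
#' @param g g-ratio (default 0.7, the literature optimum used for human
#'   pathways).
#' @return Named vector `c(min, max)` of diameters, \eqn{\mu m}.
#' @export
human_extrapolation <- function(tct_range = c(5, 13),
                                length_range = c(111.4, 122.4), g = 0.7) {
  if (tct_range[1] > tct_range[2] || length_range[1] > length_range[2])
    stop("inverted range")
  c(min = predict_diameter(tct_range[2], length_range[1], g),
    max = predict_diameter(tct_range[1], length_range[2], g))
}
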