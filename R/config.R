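#' Default run configuration
#'
#' All thresholds and constants used downstream, with defaults equal to the
#' study values where one is printed: morphometry coverage/eccentricity
#' thresholds (0.95/0.92 Epon, 0.85/0.975 Cryo), border margin 4 px, the
#' sub-resolution diameter discard limit 0.1 um, g-ratio 0.64 (cohort mean)
#' and 0.7 (human extrapolation), tract length 11.47 mm, SNR 50, and the
#' D0 policy (fixed value in um^2/ms, or "auto" for a tensor fit).
#'
#' @param seed Integer RNG seed recorded with every run.
#' @param out_dir Output directory for resolved configs and reports.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(seed = 1L, out_dir = ".") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    D0 = 0.6,                 # um^2/ms, fixed intrinsic diffusivity policy
    D0_policy = "fixed",      # or "auto": DTI principal eigenvalue over ROI
    snr = 50,
    g_ratio = 0.64,
    g_ratio_human = 0.7,
    tract_length_mm = 11.47,
    discard_below_um = 0.1,
    kde = list(bandwidth = "nrd0", n_grid = 512L),
    morpho = list(
      epon = list(coverage_min = 0.95, eccentricity_max = 0.92),
      cryo = list(coverage_min = 0.85, eccentricity_max = 0.975),
      border_px = 4L, min_area_px = 10L),
    sensitivity = list(d_min = 0.2, d_max = 15.0, d_step = 0.2,
                       n_repeats = 50L, rel_err_threshold = 0.25,
                       noise_mode = "per_direction")
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Values present in the file override the documented defaults; everything
#' else keeps its default, so a resolved config is always complete.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  out <- merge_lists(unclass(cfg), user)
  out$seed <- as.integer(out$seed)
  structure(out, class = "run_config")
}

#' Write the fully-resolved configuration and a run log
#'
#' Every pipeline run can persist the exact configuration (including the
#' seed) it executed with, for reproducibility of stochastic stages.
#'
#' @param config A `run_config`.
#' @param dir Directory to write `resolved_config.yaml` and append
#'   `run_log.txt` in; created if missing.
#' @param message Free-text log line.
#' @return The resolved config path, invisibly.
#' @export
write_resolved_config <- function(config, dir = config$out_dir,
                                  message = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "resolved_config.yaml")
  yaml::write_yaml(unclass(config), path)
  cat(sprintf("[%s] seed=%d %s\n",
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), config$seed, message),
      file = file.path(dir, "run_log.txt"), append = TRUE)
  invisible(path)
}
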