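#' Multi-trial evoked local-field-potential recording
#'
#' @param data Numeric array trials x channels x samples (a matrix is taken
#'   as trials x samples with one channel), microvolts.
#' @param fs Sampling rate, Hz.
#' @param stim_index Sample index of stimulus onset (1-based).
#' @param baseline_window Baseline interval relative to the stimulus, ms
#'   (default -50 to 0).
#' @return An `lfp_trace`.
#' @export
lfp_trace <- function(data, fs, stim_index, baseline_window = c(-50, 0)) {
  if (is.matrix(data)) {
    dn <- dim(data)
    dim(data) <- c(dn[1], 1L, dn[2])
  }
  stopifnot(length(dim(data)) == 3)
  if (fs <= 0) stop("fs must be positive")
  if (stim_index < 1 || stim_index > dim(data)[3])
    stop("stim_index outside record")
  if (dim(data)[1] < 1 || dim(data)[2] < 1)
    stop("need at least one trial and one channel")
  structure(list(data = data, fs = fs, stim_index = as.integer(stim_index),
                 baseline_window = baseline_window),
            class = "lfp_trace")
}

#' @export
print.lfp_trace <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("lfp_trace: %d trials x %d channels x %d samples at %g Hz (stim at %d)\n",
              d[1], d[2], d[3], x$fs, x$stim_index))
  invisible(x)
}

#' Average channels and trials, then baseline-correct
#'
#' Channels are averaged within each trial, trials are averaged, and the mean
#' over the baseline window is subtracted.
#'
#' @param trace An `lfp_trace`.
#' @return Numeric vector, one value per sample.
#' @export
average_and_baseline <- function(trace) {
  stopifnot(inherits(trace, "lfp_trace"))
  per_trial <- apply(trace$data, c(1, 3), mean) # trials x samples
  avg <- colMeans(per_trial)
  i0 <- trace$stim_index + round(trace$baseline_window[1] * trace$fs / 1e3)
  i1 <- trace$stim_index + round(trace$baseline_window[2] * trace$fs / 1e3)
  if (i0 < 1 || i1 > length(avg) || i1 < i0)
    stop("baseline window outside record")
  avg - mean(avg[i0:i1])
}

#' Detect the first positive (P1) and most negative (N1) deflections
#'
#' P1 is the first strict local maximum inside the open window (+1, +9) ms
#' after the stimulus whose amplitude is positive and exceeds the detection
#' floor; N1 is the global minimum in (+5, +20) ms, which must fall below
#' the negative floor. The floor defaults to three times the pre-stimulus
#' standard deviation of the averaged trace, so residual averaging noise
#' does not masquerade as the first peak; set `min_amplitude = 0` for the
#' strict any-positive-local-maximum rule. An undetectable P1 or N1 is
#' flagged rather than raising an error, mirroring recordings with no
#' measurable transcallosal response.
#'
#' @param mean_trace Averaged, baseline-corrected trace (vector).
#' @param fs Sampling rate, Hz.
#' @param stim_index Stimulus-onset sample (1-based).
#' @param p1_window,n1_window Detection windows, ms after stimulus.
#' @param min_amplitude Detection floor, \eqn{\mu V}; `NULL` (default) uses
#'   3 x SD of the pre-stimulus samples (0 when there are fewer than two).
#' @param smooth_ms Width of a centered moving-average applied before
#'   detection, ms (default 0: no smoothing). At high sampling rates a
#'   fraction of a millisecond suppresses local maxima that residual
#'   averaging noise superimposes on the rising edge of a deflection.
#' @param peak_window_ms Half-width of the neighbourhood a P1 candidate must
#'   dominate, ms. The default 0 uses the strict rule (greater than the two
#'   adjacent samples, ties broken by the earliest sample); at high sampling
#'   rates a half-width of ~1 ms rejects sample-scale noise blips on the
#'   rising edge, which adjacent-sample comparisons cannot.
#' @return A `peak_set`: `p1_latency`, `p1_amplitude`, `n1_latency`,
#'   `n1_amplitude` (latencies in ms, NA when absent), `has_p1`, `has_n1`.
#' @export
detect_peaks <- function(mean_trace, fs, stim_index,
                         p1_window = c(1, 9), n1_window = c(5, 20),
                         min_amplitude = NULL, smooth_ms = 0,
                         peak_window_ms = 0) {
  if (smooth_ms > 0) {
    w <- max(1L, round(smooth_ms * fs / 1e3))
    if (w %% 2 == 0) w <- w + 1L
    sm <- as.numeric(stats::filter(mean_trace, rep(1 / w, w), sides = 2))
    mean_trace <- ifelse(is.na(sm), mean_trace, sm)
  }
  n <- length(mean_trace)
  to_idx <- function(ms) stim_index + round(ms * fs / 1e3)
  if (to_idx(max(p1_window[2], n1_window[2])) > n)
    stop("detection window exceeds record")
  ms_at <- function(i) (i - stim_index) * 1e3 / fs
  if (is.null(min_amplitude)) {
    pre <- mean_trace[seq_len(max(stim_index - 1L, 0L))]
    min_amplitude <- if (length(pre) > 1) 3 * sd(pre) else 0
  }
  ## P1: first local max above the floor, inside the open window; the
  ## candidate must dominate its +/- k-sample neighbourhood
  k <- max(1L, round(peak_window_ms * fs / 1e3))
  i_lo <- to_idx(p1_window[1]); i_hi <- to_idx(p1_window[2])
  p1_i <- NA_integer_
  for (i in seq(max(i_lo + 1L, 2L), min(i_hi - 1L, n - 1L))) {
    win <- mean_trace[max(1L, i - k):min(n, i + k)]
    if (mean_trace[i] > min_amplitude &&
        mean_trace[i] > mean_trace[i - 1] &&
        mean_trace[i] >= max(win)) { p1_i <- i; break }
  }
  ## N1: global minimum in window, below the negative floor
  j_lo <- to_idx(n1_window[1]); j_hi <- to_idx(n1_window[2])
  seg <- mean_trace[j_lo:j_hi]
  n1_i <- j_lo + which.min(seg) - 1L
  has_n1 <- mean_trace[n1_i] < -min_amplitude
  structure(list(
    p1_latency = if (is.na(p1_i)) NA_real_ else ms_at(p1_i),
    p1_amplitude = if (is.na(p1_i)) NA_real_ else mean_trace[p1_i],
    n1_latency = if (has_n1) ms_at(n1_i) else NA_real_,
    n1_amplitude = if (has_n1) mean_trace[n1_i] else NA_real_,
    has_p1 = !is.na(p1_i), has_n1 = has_n1),
    class = "peak_set")
}

#' Trial-to-trial reliability at the N1 latency (coefficient of variation)
#'
#' Samples each trial's channel-averaged amplitude at the detected N1 latency
#' and returns SD divided by the absolute mean. A condition is reliable when
#' the CoV is below 1.00; a zero mean amplitude gives an infinite CoV
#' (unreliable).
#'
#' @param trace An `lfp_trace`.
#' @param n1_latency Detected N1 latency, ms after stimulus.
#' @return List: `cov`, `reliable`, `amplitudes` (per trial, baseline
#'   corrected per trial over the trace's baseline window).
#' @export
reliability_cov <- function(trace, n1_latency) {
  stopifnot(inherits(trace, "lfp_trace"))
  if (is.na(n1_latency)) stop("n1 latency not detected")
  per_trial <- apply(trace$data, c(1, 3), mean) # trials x samples
  i0 <- trace$stim_index + round(trace$baseline_window[1] * trace$fs / 1e3)
  i1 <- trace$stim_index + round(trace$baseline_window[2] * trace$fs / 1e3)
  if (i0 >= 1 && i1 >= i0)
    per_trial <- per_trial - rowMeans(per_trial[, i0:i1, drop = FALSE])
  idx <- trace$stim_index + round(n1_latency * trace$fs / 1e3)
  if (idx < 1 || idx > ncol(per_trial)) stop("latency outside record")
  amp <- per_trial[, idx]
  m <- mean(amp)
  cov <- if (m == 0) Inf else sd(amp) / abs(m)
  list(cov = cov, reliable = is.finite(cov) && cov < 1.00, amplitudes = amp)
}

#' N1 onset latency (experimental)
#'
#' First crossing into negative territory after P1 and before the N1 peak.
#' The onset definition is not standardized; treat as exploratory.
#'
#' @param mean_trace Averaged, baseline-corrected trace.
#' @param fs Sampling rate, Hz.
#' @param stim_index Stimulus-onset sample.
#' @param peaks A `peak_set` with detected P1 and N1.
#' @return Onset latency in ms, or NA.
#' @export
n1_onset <- function(mean_trace, fs, stim_index, peaks) {
  if (!peaks$has_p1 || !peaks$has_n1) return(NA_real_)
  i_p1 <- stim_index + round(peaks$p1_latency * fs / 1e3)
  i_n1 <- stim_index + round(peaks$n1_latency * fs / 1e3)
  for (i in seq(i_p1, i_n1)) {
    if (mean_trace[i] < 0) return((i - stim_index) * 1e3 / fs)
  }
  NA_real_
}
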