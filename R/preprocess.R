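#' Zero-phase low-pass Butterworth filtering of all channels
#'
#' Designs a low-pass Butterworth filter of the given order and applies it
#' forward and backward ([signal::filtfilt()]) to every channel, which
#' cancels the group delay exactly (zero phase) while squaring the magnitude
#' response: the effective attenuation is `|H(f)|^2` with
#' `|H(f)|^2 = 1 / (1 + (f/fc)^(2*order))`, and the DC gain stays 1.
#'
#' Because forward-backward filtering is sensitive to edge transients, each
#' channel is extended by odd reflection (point symmetry about the first and
#' last sample) over `pad` samples before filtering; the extension is dropped
#' afterwards. The default pad of 200 samples (20 s at 10 Hz) brings the
#' residual edge error on a constant signal below 1e-7 for the default
#' 10th-order, 0.8 Hz design.
#'
#' @param rec a `nirs_recording`.
#' @param order filter order of the designed (one-pass) filter; default 10.
#' @param cutoff_hz -3 dB cutoff frequency of the one-pass design; default
#'   0.8 Hz.
#' @param pad odd-reflection padding length in samples.
#' @return the filtered recording; the operation is logged in
#'   `$provenance`.
#' @export
lowpass_zero_phase <- function(rec, order = 10, cutoff_hz = 0.8, pad = 200) {
  stopifnot(inherits(rec, "nirs_recording"))
  fs <- rec$sampling_rate
  if (fs <= 2 * cutoff_hz)
    stop("sampling rate must exceed twice the cutoff frequency")
  n <- nrow(rec$data)
  pad <- min(pad, n - 1L)
  if (n < 3L * (order + 1L))
    stop("recording too short for stable zero-phase filtering")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  for (ch in channels(rec)) {
    x <- rec$data[[ch]]
    pre <- 2 * x[1] - x[(pad + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - pad)]
    y <- signal::filtfilt(bf, c(pre, x, post))
    rec$data[[ch]] <- y[(pad + 1L):(pad + n)]
  }
  rec$provenance <- c(rec$provenance,
                      sprintf("lowpass_zero_phase: order=%d cutoff_hz=%g pad=%d",
                              order, cutoff_hz, pad))
  rec
}

#' Baseline normalization of all channels
#'
#' Subtracts from every channel (TSI included) its mean over the baseline
#' window, expressing each signal as the magnitude difference from resting
#' values. The default window `[150, 750)` s is the central ten minutes of a
#' 15-min baseline, avoiding settling effects at both ends. Normalizing an
#' already normalized recording is a contract violation and raises an error.
#'
#' @param rec a `nirs_recording`.
#' @param window numeric length-2, the half-open `[t_start, t_end)` window in
#'   seconds.
#' @return the normalized recording, with `$normalized = TRUE` and
#'   `$baseline_window` set. A `dhb` channel is added (difference of the
#'   normalized concentration channels) if not already present.
#' @export
normalize_to_baseline <- function(rec, window = c(150, 750)) {
  stopifnot(inherits(rec, "nirs_recording"), length(window) == 2L)
  if (rec$normalized)
    stop("recording is already normalized; refusing to normalize twice")
  tt <- rec$data$time
  if (window[1] < tt[1] - 1e-9 || window[2] > tt[length(tt)] + 1 / rec$sampling_rate)
    stop("baseline window outside the recording")
  idx <- window_idx(tt, window[1], window[2])
  if (length(idx) < 2L) stop("baseline window contains too few samples")
  for (ch in channels(rec))
    rec$data[[ch]] <- rec$data[[ch]] - mean(rec$data[[ch]][idx], na.rm = TRUE)
  if (!"dhb" %in% channels(rec))
    rec$data$dhb <- compute_delta_hb(rec$data$o2hb, rec$data$hhb)
  rec$normalized <- TRUE
  rec$baseline_window <- window
  rec$provenance <- c(rec$provenance,
                      sprintf("normalize_to_baseline: window=[%g,%g)",
                              window[1], window[2]))
  rec
}
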