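#' Locate a deoxy-/reoxygenation curve by the 10% threshold rule
#'
#' Within a phase window, the curve peak is the sample of largest absolute
#' deviation from the local pre-event level (by default the value of the
#' first sample in the window). The curve start is the last time before the
#' peak at which the absolute deviation is at or below `threshold` times the
#' peak deviation, and the end is the first such time after the peak; both
#' are refined by linear interpolation between the bracketing samples. A
#' curve that never returns below the threshold ends at the window end
#' (plateau fallback); a window whose peak deviation is below `noise_floor`
#' yields a "no event" result.
#'
#' The rule is scale-free: multiplying the series by any positive constant
#' leaves all three times unchanged.
#'
#' @param time,series the sampled signal (normalized channel).
#' @param window half-open `[t0, t1)` phase window, seconds.
#' @param threshold start/end fraction of the peak deviation (default 0.10).
#' @param level pre-event reference level; default the first sample in the
#'   window.
#' @param noise_floor peak deviations below this are treated as "no event".
#' @return list with `start`, `peak`, `end` (times, s), `peak_value`,
#'   `level`, and logical `no_event`, `end_fallback`.
#' @export
detect_curve_bounds <- function(time, series, window, threshold = 0.10,
                                level = NULL, noise_floor = 1e-8) {
  idx <- window_idx(time, window[1], window[2])
  if (length(idx) < 2L) stop("phase window contains too few samples")
  tt <- time[idx]; yy <- series[idx]
  if (is.null(level)) level <- yy[1]
  dev <- yy - level
  ipk <- which.max(abs(dev))  # ties break to the earliest time
  pk <- abs(dev[ipk])
  if (!is.finite(pk) || pk < noise_floor)
    return(list(start = NA_real_, peak = NA_real_, end = NA_real_,
                peak_value = NA_real_, level = level,
                no_event = TRUE, end_fallback = FALSE))
  thr <- threshold * pk
  adev <- abs(dev)
  # start: last sample at/below threshold before the peak, interpolated
  pre <- which(adev[seq_len(ipk)] <= thr)
  if (length(pre) == 0L) {
    start <- tt[1]
  } else {
    i0 <- max(pre)
    start <- if (i0 == ipk) tt[i0] else
      interp_crossing(tt[i0:(i0 + 1L)], adev[i0:(i0 + 1L)], thr, "left")
  }
  post <- which(adev[ipk:length(adev)] <= thr)
  if (length(post) == 0L) {
    end <- window[2]
    fallback <- TRUE
  } else {
    i1 <- ipk + min(post) - 1L
    end <- if (i1 == ipk) tt[i1] else
      interp_crossing(tt[(i1 - 1L):i1], adev[(i1 - 1L):i1], thr, "right")
    fallback <- FALSE
  }
  list(start = start, peak = tt[ipk], end = end,
       peak_value = yy[ipk], level = level,
       no_event = FALSE, end_fallback = fallback)
}

#' Hyperemia spike within a reperfusion window
#'
#' The spike is the global maximum of the (normalized) series within the
#' first `horizon_s` seconds of the reperfusion window; ties break to the
#' earliest time. A maximum at or below zero means oxygenation never
#' exceeded baseline (legal for venous-only pressures) and is flagged as
#' "no hyperemia".
#'
#' @param time,series normalized TSI (or O2Hb) channel.
#' @param window reperfusion `[t0, t1)` window, seconds.
#' @param horizon_s search horizon after the window start (default 120).
#' @return list with `spike_time`, `spike_value`, logical `no_hyperemia`.
#' @export
find_spike <- function(time, series, window, horizon_s = 120) {
  idx <- window_idx(time, window[1], min(window[2], window[1] + horizon_s))
  if (length(idx) < 2L) stop("reperfusion window contains too few samples")
  yy <- series[idx]
  imax <- which.max(yy)
  val <- yy[imax]
  if (!is.finite(val) || val <= 0)
    return(list(spike_time = NA_real_, spike_value = val,
                no_hyperemia = TRUE))
  list(spike_time = time[idx][imax], spike_value = val, no_hyperemia = FALSE)
}

#' Nearest zero-crossing to the left of the hyperemia spike
#'
#' Returns the linearly interpolated time of the sign change of the series
#' closest to `spike_time` on its left, searched from `window_start`. If the
#' series never changes sign there, the window start is returned with a
#' warning (fallback contract).
#'
#' @param time,series normalized channel.
#' @param spike_time spike time, s.
#' @param window_start left boundary of the search, s.
#' @return list with `time` and logical `fallback`.
#' @export
zero_crossing_before <- function(time, series, spike_time, window_start) {
  idx <- which(time >= window_start & time <= spike_time)
  if (length(idx) < 2L) stop("empty search window for zero crossing")
  zc <- interp_crossing(time[idx], series[idx], 0, from = "right")
  if (is.na(zc)) {
    warning("no zero crossing before the spike; using the window start")
    return(list(time = window_start, fallback = TRUE))
  }
  list(time = zc, fallback = FALSE)
}

#' First 63% decay of the hyperemia spike
#'
#' First time after `spike_time` at which the series has lost `decay_frac`
#' of the spike amplitude, i.e. falls to `(1 - decay_frac) * spike_value`
#' (linear interpolation between samples). If the threshold is never reached
#' before `phase_end`, that time is returned with a flag.
#'
#' @param time,series normalized channel.
#' @param spike_time,spike_value the spike (value must be positive).
#' @param phase_end end of the reperfusion phase, s.
#' @param decay_frac decay fraction (default 0.63).
#' @return list with `time` and logical `fallback`.
#' @export
decay63_after <- function(time, series, spike_time, spike_value, phase_end,
                          decay_frac = 0.63) {
  if (!is.finite(spike_value) || spike_value <= 0)
    stop("decay63_after requires a positive spike value")
  idx <- which(time >= spike_time & time < phase_end)
  if (length(idx) < 2L) stop("empty search window after the spike")
  target <- (1 - decay_frac) * spike_value
  tt <- time[idx]; yy <- series[idx]
  below <- which(yy <= target)
  if (length(below) == 0L)
    return(list(time = phase_end, fallback = TRUE))
  i1 <- min(below)
  tm <- if (i1 == 1L) tt[1] else
    interp_crossing(tt[(i1 - 1L):i1], yy[(i1 - 1L):i1], target, "left")
  list(time = tm, fallback = FALSE)
}

#' Event marks for every occlusion-reperfusion cycle of a recording
#'
#' Applies the curve-bound, spike, zero-crossing and decay rules per cycle
#' and channel, producing the audit table consumed by feature extraction.
#' Occlusion and reperfusion windows are offset by the schedule's cuff ramp
#' before searching, since inflation/deflation is not instantaneous.
#'
#' @param rec a normalized `nirs_recording`.
#' @param schedule the protocol schedule.
#' @param threshold curve start/end fraction (default 0.10).
#' @param decay_frac spike decay fraction (default 0.63).
#' @param spike_horizon_s hyperemia search horizon, s.
#' @param noise_floor no-event floor passed to [detect_curve_bounds()].
#' @return data frame, one row per cycle x channel, with deoxy/reoxy curve
#'   bounds and (for TSI) spike, zero-crossing and decay-63 times.
#' @export
locate_cycle_events <- function(rec, schedule, threshold = 0.10,
                                decay_frac = 0.63, spike_horizon_s = 120,
                                noise_floor = 1e-8) {
  stopifnot(inherits(rec, "nirs_recording"))
  if (!rec$normalized)
    stop("event detection requires a baseline-normalized recording")
  ramp <- attr(schedule, "cuff_ramp_s")
  cyc <- schedule_cycles(schedule)
  tt <- rec$data$time
  rows <- list()
  for (i in seq_len(nrow(cyc))) {
    wocc <- c(cyc$occl_start[i] + ramp, cyc$occl_end[i])
    wrep <- c(cyc$occl_end[i] + ramp, cyc$reperf_end[i])
    for (ch in channels(rec)) {
      y <- rec$data[[ch]]
      deoxy <- detect_curve_bounds(tt, y, wocc, threshold,
                                   noise_floor = noise_floor)
      reoxy <- detect_curve_bounds(tt, y, wrep, threshold,
                                   noise_floor = noise_floor)
      row <- data.frame(
        cycle = i, channel = ch,
        deoxy_start = deoxy$start, deoxy_peak = deoxy$peak,
        deoxy_end = deoxy$end, deoxy_no_event = deoxy$no_event,
        reoxy_start = reoxy$start, reoxy_peak = reoxy$peak,
        reoxy_end = reoxy$end, reoxy_no_event = reoxy$no_event,
        spike_time = NA_real_, spike_value = NA_real_,
        no_hyperemia = NA, zero_cross = NA_real_, decay63 = NA_real_,
        stringsAsFactors = FALSE)
      if (ch == "tsi") {
        sp <- find_spike(tt, y, wrep, spike_horizon_s)
        row$spike_time <- sp$spike_time
        row$spike_value <- sp$spike_value
        row$no_hyperemia <- sp$no_hyperemia
        if (!sp$no_hyperemia) {
          zc <- suppressWarnings(
            zero_crossing_before(tt, y, sp$spike_time, wrep[1]))
          d63 <- decay63_after(tt, y, sp$spike_time, sp$spike_value,
                               cyc$reperf_end[i], decay_frac)
          row$zero_cross <- zc$time
          row$decay63 <- d63$time
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
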