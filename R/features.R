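#' Extrema of a channel within a phase window
#'
#' @param time,series sampled channel.
#' @param window half-open `[t0, t1)` window, seconds.
#' @return list with `min`, `max`, `t_min`, `t_max`.
#' @export
phase_extrema <- function(time, series, window) {
  idx <- window_idx(time, window[1], window[2])
  if (length(idx) == 0L) stop("empty phase window")
  yy <- series[idx]
  imin <- which.min(yy); imax <- which.max(yy)
  list(min = yy[imin], max = yy[imax],
       t_min = time[idx][imin], t_max = time[idx][imax])
}

#' Signed occlusion area under the curve
#'
#' Trapezoidal integral of the baseline-normalized signal over the occlusion
#' window. The sign is retained: deoxygenation gives negative areas on TSI
#' and O2Hb and positive areas on HHb.
#'
#' @param time,series normalized channel.
#' @param window integration window `[t0, t1]`, seconds.
#' @return signed area in channel-units x s (reported as a.u.).
#' @export
occlusion_auc <- function(time, series, window) {
  idx <- window_idx(time, window[1], window[2])
  if (length(idx) < 2L) stop("occlusion window shorter than 2 samples")
  auc_between(time, series, window[1], window[2])
}

#' Reoxygenation (PORH) area under the curve
#'
#' Trapezoidal integral of the normalized signal between the zero-crossing
#' preceding the hyperemia spike and the first 63% decay after it. Bounds
#' may fall between samples; endpoint values are linearly interpolated.
#'
#' @param time,series normalized channel.
#' @param zero_cross_time,decay63_time integration bounds, seconds
#'   (`zero_cross_time <= decay63_time`).
#' @return signed area (non-negative when the signal is non-negative on the
#'   interval).
#' @export
porh_auc <- function(time, series, zero_cross_time, decay63_time) {
  if (decay63_time < zero_cross_time)
    stop("inverted PORH bounds (zero crossing after decay point)")
  auc_between(time, series, zero_cross_time, decay63_time)
}

#' 63% time constant of the occlusion response
#'
#' Elapsed time from the window start (the occlusion onset offset by the
#' cuff ramp) until the series first attains `decay_frac` (63%) of its
#' extreme deviation within the window, with linear interpolation between
#' samples. The deviation is measured from the value at the window start;
#' `direction = "rise"` tracks upward deviations (HHb), `"fall"` downward
#' ones (TSI, O2Hb, dHb).
#'
#' @param time,series normalized channel.
#' @param window occlusion window `[t0, t1)`, seconds.
#' @param direction `"rise"` or `"fall"`.
#' @param decay_frac target fraction of the extreme deviation.
#' @param noise_floor extreme deviations below this are flagged (no event).
#' @return list with `tau` (seconds, `NA` when flagged) and `flagged`.
#' @export
time_constant_63 <- function(time, series, window,
                             direction = c("rise", "fall"),
                             decay_frac = 0.63, noise_floor = 1e-8) {
  direction <- match.arg(direction)
  idx <- window_idx(time, window[1], window[2])
  if (length(idx) < 2L) stop("occlusion window contains too few samples")
  tt <- time[idx]
  dev <- series[idx] - series[idx][1]
  if (direction == "fall") dev <- -dev
  ext <- max(dev)
  if (!is.finite(ext) || ext < noise_floor)
    return(list(tau = NA_real_, flagged = TRUE))
  cross <- interp_crossing(tt, dev, decay_frac * ext, from = "left")
  list(tau = cross - tt[1], flagged = FALSE)
}

#' 30-s slope of a deoxy- or reoxygenation curve
#'
#' Ordinary least-squares slope of the series over the first 30 s following
#' the detected curve start.
#'
#' @param time,series sampled channel.
#' @param curve_start_time detected curve start, seconds.
#' @param duration_s regression window length (default 30).
#' @return list with `slope` (channel units per second, `NA` when flagged)
#'   and `flagged` (insufficient data).
#' @export
slope_30s <- function(time, series, curve_start_time, duration_s = 30) {
  if (is.na(curve_start_time))
    return(list(slope = NA_real_, flagged = TRUE))
  idx <- which(time >= curve_start_time &
                 time <= curve_start_time + duration_s)
  dtm <- stats::median(diff(time))
  if (length(idx) < 2L ||
      time[max(idx)] - curve_start_time < duration_s - dtm - 1e-9)
    return(list(slope = NA_real_, flagged = TRUE))
  tt <- time[idx]; yy <- series[idx]
  list(slope = stats::cov(tt, yy) / stats::var(tt), flagged = FALSE)
}

#' Ankle-brachial index
#'
#' Ratio of the highest ankle systolic pressure to the highest brachial
#' systolic pressure; a resting vascular screening metric (values near 1 are
#' normal).
#'
#' @param ankle_sbps,brachial_sbps positive pressures, mmHg (non-empty).
#' @return the ratio.
#' @examples
#' compute_abi(c(120, 118), c(116, 114))  # 1.034
#' @export
compute_abi <- function(ankle_sbps, brachial_sbps) {
  if (length(ankle_sbps) == 0L || length(brachial_sbps) == 0L)
    stop("pressure lists must be non-empty")
  if (any(ankle_sbps <= 0) || any(brachial_sbps <= 0))
    stop("pressures must be positive")
  max(ankle_sbps) / max(brachial_sbps)
}

# direction of the occlusion response per channel
deoxy_direction <- function(ch) if (ch == "hhb") "rise" else "fall"

#' Per-cycle hemodynamic features of a recording
#'
#' Computes, for every occlusion-reperfusion cycle and every channel, the
#' cycle extrema, signed occlusion AUC, 63% time constant, and 30-s
#' deoxygenation/reoxygenation slopes; plus the TSI hyperemia metrics (spike
#' maximum, PORH AUC between the pre-spike zero-crossing and the post-spike
#' 63% decay, and the PORH rise time constant from the reoxygenation curve
#' start to 63% of the spike value). Fallback conditions (no event, no
#' hyperemia) yield `NA` for the affected features.
#'
#' @param rec a filtered, baseline-normalized `nirs_recording`.
#' @param schedule protocol schedule.
#' @param threshold curve start/end fraction.
#' @param decay_frac 63% fraction for time constants and spike decay.
#' @param spike_horizon_s hyperemia search horizon, s.
#' @param noise_floor no-event floor for flat windows.
#' @return list with `features` (data frame, one row per cycle) and `marks`
#'   (the [locate_cycle_events()] audit table).
#' @export
extract_cycle_features <- function(rec, schedule, threshold = 0.10,
                                   decay_frac = 0.63, spike_horizon_s = 120,
                                   noise_floor = 1e-8) {
  stopifnot(inherits(rec, "nirs_recording"))
  if (!rec$normalized)
    stop("feature extraction requires a baseline-normalized recording")
  marks <- locate_cycle_events(rec, schedule, threshold, decay_frac,
                               spike_horizon_s, noise_floor)
  ramp <- attr(schedule, "cuff_ramp_s")
  cyc <- schedule_cycles(schedule)
  tt <- rec$data$time
  rows <- vector("list", nrow(cyc))
  for (i in seq_len(nrow(cyc))) {
    wocc <- c(cyc$occl_start[i] + ramp, cyc$occl_end[i])
    wcycle <- c(cyc$occl_start[i], cyc$reperf_end[i])
    row <- list(cycle = i)
    for (ch in channels(rec)) {
      y <- rec$data[[ch]]
      mk <- marks[marks$cycle == i & marks$channel == ch, ]
      ex <- phase_extrema(tt, y, wcycle)
      row[[paste0(ch, "_min")]] <- ex$min
      row[[paste0(ch, "_max")]] <- ex$max
      row[[paste0(ch, "_auc")]] <- occlusion_auc(tt, y, wocc)
      tau <- time_constant_63(tt, y, wocc, deoxy_direction(ch),
                              decay_frac, noise_floor)
      row[[paste0(ch, "_tau")]] <- tau$tau
      row[[paste0(ch, "_slope_deoxy")]] <-
        slope_30s(tt, y, mk$deoxy_start)$slope
      row[[paste0(ch, "_slope_reoxy")]] <-
        slope_30s(tt, y, mk$reoxy_start)$slope
      if (ch == "tsi") {
        if (isTRUE(mk$no_hyperemia) || is.na(mk$spike_value)) {
          row$tsi_max_porh <- NA_real_
          row$tsi_auc_porh <- NA_real_
          row$tsi_tau_porh <- NA_real_
        } else {
          row$tsi_max_porh <- mk$spike_value
          # a fallback decay point at the phase end may lie one sample past
          # the half-open grid; clamp the bounds to the sampled record
          row$tsi_auc_porh <- porh_auc(tt, y,
                                       max(mk$zero_cross, tt[1]),
                                       min(mk$decay63, tt[length(tt)]))
          row$tsi_tau_porh <- if (is.na(mk$reoxy_start)) NA_real_ else {
            ridx <- which(tt >= mk$reoxy_start & tt <= mk$spike_time)
            if (length(ridx) < 2L) NA_real_ else {
              cr <- interp_crossing(tt[ridx], y[ridx],
                                    decay_frac * mk$spike_value, "left")
              if (is.na(cr)) NA_real_ else cr - mk$reoxy_start
            }
          }
        }
      }
    }
    rows[[i]] <- as.data.frame(row)
  }
  list(features = do.call(rbind, rows), marks = marks)
}

#' Average the three cycles into one session value per parameter
#'
#' Arithmetic mean per parameter over the non-flagged (non-`NA`) cycles;
#' the number of contributing cycles is recorded per parameter. A parameter
#' flagged in every cycle stays missing and is reported in a message.
#'
#' @param cycle_features the `features` data frame from
#'   [extract_cycle_features()].
#' @return one-row data frame of parameter means, with a `counts` attribute
#'   (contributing cycles per parameter).
#' @export
average_cycles <- function(cycle_features) {
  stopifnot(is.data.frame(cycle_features), nrow(cycle_features) >= 1L)
  pcols <- setdiff(names(cycle_features), "cycle")
  means <- vapply(cycle_features[pcols], function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  counts <- vapply(cycle_features[pcols], function(v) sum(!is.na(v)),
                   integer(1))
  if (any(counts == 0L))
    message("parameter(s) missing in all cycles: ",
            paste(pcols[counts == 0L], collapse = ", "))
  out <- as.data.frame(as.list(means))
  attr(out, "counts") <- counts
  out
}
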