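# Ground-truth feature oracle for the synthetic generator.
#
# All quantities are derived from the continuous closed-form cycle model with
# root finding (uniroot), golden-section optimization (optimize) and
# quadrature (integrate) -- never through the sampled-signal extraction code,
# so the two routes stay independent and can be compared in validation.

# OLS slope of the model f over [s, s+w], evaluated on the acquisition grid
# (multiples of dt) exactly as the sampled-signal estimator sees it; textbook
# closed form, independent of the extraction code
sampled_ols_slope <- function(f, s, w = 30, dt = 0.1) {
  k0 <- ceiling((s - 1e-9) / dt)
  tt <- seq(k0 * dt, s + w + 1e-9, by = dt)
  yy <- f(tt)
  sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
}

root_on <- function(g, lo, hi) {
  stats::uniroot(g, c(lo, hi), tol = 1e-9)$root
}

#' Closed-form ground-truth features of a simulated session
#'
#' Evaluates, for every occlusion-reperfusion cycle of the noise-free model
#' implied by `params` and `schedule`, the same quantities the extraction
#' pipeline measures: per-channel extrema, occlusion AUC, 63% time constant,
#' 30-s deoxygenation and reoxygenation slopes, and the TSI hyperemia
#' (spike value/time, zero-crossing, 63% decay point, PORH AUC and rise time
#' constant). Everything is computed from the continuous model by root
#' finding, optimization and quadrature, independently of the sampled-signal
#' extraction path.
#'
#' @param params a [sim_params()] with `cuff_pressure` set.
#' @param schedule the protocol schedule.
#' @param sampling_rate acquisition rate (Hz) defining the sample grid on
#'   which the 30-s OLS slopes are evaluated.
#' @param threshold curve start/end detection fraction (default 0.10).
#' @param decay_frac decay fraction defining the 63% points (default 0.63).
#' @param spike_horizon_s hyperemia search horizon after deflation, seconds.
#' @return data frame, one row per cycle, with the extraction pipeline's
#'   column names; PORH columns are `NA` when the model produces no
#'   hyperemia (completeness near zero and no overshoot).
#' @export
true_cycle_features <- function(params, schedule = build_schedule(),
                                sampling_rate = 10,
                                threshold = 0.10, decay_frac = 0.63,
                                spike_horizon_s = 120) {
  stopifnot(inherits(params, "sim_params"))
  ramp <- attr(schedule, "cuff_ramp_s")
  cyc <- schedule_cycles(schedule)
  cc <- occlusion_completeness(params$cuff_pressure, params$sbp,
                               params$k_sigmoid)
  out <- vector("list", nrow(cyc))
  for (i in seq_len(nrow(cyc))) {
    t0 <- cyc$occl_start[i]; t1 <- cyc$occl_end[i]; t2 <- cyc$reperf_end[i]
    m <- cycle_model(params, cc, t0, t1, t2, ramp)
    row <- list(cycle = i, completeness = cc)
    # TSI hyperemia quantities first (shared with the tsi channel loop)
    spike <- stats::optimize(m$tsi, c(t1 + ramp, t1 + ramp + spike_horizon_s),
                             maximum = TRUE, tol = 1e-7)
    has_porh <- spike$objective > 0
    row$tsi_spike_time <- if (has_porh) spike$maximum else NA_real_
    row$tsi_max_porh <- if (has_porh) spike$objective else NA_real_
    if (has_porh) {
      zc <- root_on(m$tsi, t1, spike$maximum)
      d63 <- root_on(function(t) m$tsi(t) - (1 - decay_frac) * spike$objective,
                     spike$maximum, t2 - 1e-6)
      row$tsi_zero_cross <- zc
      row$tsi_decay63 <- d63
      row$tsi_auc_porh <- stats::integrate(m$tsi, zc, d63,
                                           rel.tol = 1e-10,
                                           subdivisions = 400L)$value
    } else {
      row$tsi_zero_cross <- NA_real_
      row$tsi_decay63 <- NA_real_
      row$tsi_auc_porh <- NA_real_
    }
    for (ch in c("tsi", "o2hb", "hhb", "dhb")) {
      f <- m[[ch]]
      occ_end_val <- f(t1 - 1e-9)
      # reperfusion extremum relative to the occluded level: hhb decays
      # through a single-trough undershoot; the others have a single-peak
      # overshoot
      if (ch == "hhb") {
        op <- stats::optimize(f, c(t1 + ramp, t2 - 1e-6), tol = 1e-7)
        rep_ext_val <- op$objective
        rep_ext_t <- op$minimum
      } else {
        op <- stats::optimize(f, c(t1 + ramp, t2 - 1e-6),
                              maximum = TRUE, tol = 1e-7)
        rep_ext_val <- op$objective
        rep_ext_t <- op$maximum
      }
      ends <- c(f(t0), occ_end_val, rep_ext_val, f(t2 - 1e-6))
      row[[paste0(ch, "_min")]] <- min(ends)
      row[[paste0(ch, "_max")]] <- max(ends)
      row[[paste0(ch, "_auc")]] <- stats::integrate(
        f, t0 + ramp, t1, rel.tol = 1e-10, subdivisions = 400L)$value
      # occlusion 63% time constant, measured from the post-ramp window start
      lev <- f(t0 + ramp)
      dev_ext <- occ_end_val - lev
      row[[paste0(ch, "_tau")]] <-
        root_on(function(t) f(t) - (lev + decay_frac * dev_ext),
                t0 + ramp, t1 - 1e-9) - (t0 + ramp)
      # deoxygenation curve start at the 10% threshold, then 30-s OLS slope
      ds <- root_on(function(t) f(t) - (lev + threshold * dev_ext),
                    t0 + ramp, t1 - 1e-9)
      row[[paste0(ch, "_deoxy_start")]] <- ds
      row[[paste0(ch, "_slope_deoxy")]] <- sampled_ols_slope(f, ds, dt = 1 / sampling_rate)
      # reoxygenation curve start and slope
      levr <- f(t1 + ramp)
      devr <- rep_ext_val - levr
      rs <- if (abs(devr) < 1e-12) NA_real_ else
        root_on(function(t) f(t) - (levr + threshold * devr),
                t1 + ramp, rep_ext_t)
      row[[paste0(ch, "_reoxy_start")]] <- rs
      row[[paste0(ch, "_slope_reoxy")]] <-
        if (is.na(rs)) NA_real_ else sampled_ols_slope(f, rs, dt = 1 / sampling_rate)
      if (ch == "tsi") {
        row$tsi_tau_porh <- if (has_porh && !is.na(rs))
          root_on(function(t) m$tsi(t) - decay_frac * spike$objective,
                  rs, spike$maximum) - rs
        else NA_real_
      }
    }
    out[[i]] <- as.data.frame(row)
  }
  do.call(rbind, out)
}
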