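#' Simulation parameters for synthetic occlusion-response recordings
#'
#' Bundles the kinetic, pressure and noise parameters of the synthetic NIRS
#' generator. The generator is a phenomenological model of the
#' occlusion-reperfusion response, not a mechanistic circulation model: during
#' occlusion HHb rises exponentially toward an amplitude set by the occlusion
#' completeness, O2Hb mirrors it with negative sign, and on deflation both
#' relax exponentially toward baseline. The hyperemic overshoot is modelled
#' as an arterial-inflow exchange: a single-peak pulse is added to the O2Hb
#' pool and subtracted from the HHb pool (total hemoglobin unchanged), which
#' lifts TSI and O2Hb above baseline with a transient HHb undershoot.
#' TSI is derived from absolute hemoglobin pools so that all channels stay
#' mutually consistent.
#'
#' @param sbp systolic blood pressure, mmHg.
#' @param cuff_pressure applied cuff pressure, mmHg (`NULL` until resolved
#'   from a group rule).
#' @param baseline_tsi resting tissue saturation index, percent.
#' @param a_art maximal arterial-occlusion HHb amplitude (device
#'   concentration units, > 0); reached as cuff pressure far exceeds SBP.
#' @param a_ven venous-occlusion HHb amplitude (>= 0); the response floor at
#'   sub-systolic pressures.
#' @param k_sigmoid width (mmHg) of the logistic transition between venous
#'   and complete occlusion.
#' @param tau_deoxy deoxygenation time constant, s.
#' @param tau_reoxy reperfusion washout time constant, s.
#' @param h_amp hyperemic overshoot amplitude on TSI, percent (scaled by the
#'   occlusion completeness).
#' @param t_peak overshoot time to peak, s.
#' @param noise_sd Gaussian noise SD per concentration channel (device
#'   units); the default 0.6 yields a baseline TSI SD of about 0.5%.
#' @param drift_slope maximal magnitude of per-channel linear drift
#'   (units/s); each session draws a rate uniformly in
#'   `[-drift_slope, drift_slope]` per channel.
#' @param pool_total total hemoglobin pool (device units) anchoring the TSI
#'   derivation; sets the TSI excursion per unit of concentration change.
#' @param baseline_offset constant added to both concentration pools
#'   (models between-session repositioning of the optode).
#' @param seed integer RNG seed, or `NULL` to draw from the current RNG
#'   stream.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(sbp = 118, cuff_pressure = NULL, baseline_tsi = 65,
                       a_art = 10, a_ven = 18, k_sigmoid = 10,
                       tau_deoxy = 150, tau_reoxy = 8,
                       h_amp = 11, t_peak = 30,
                       noise_sd = 0.6, drift_slope = 0.001,
                       pool_total = 88, baseline_offset = 0, seed = NULL) {
  p <- list(sbp = sbp, cuff_pressure = cuff_pressure,
            baseline_tsi = baseline_tsi, a_art = a_art, a_ven = a_ven,
            k_sigmoid = k_sigmoid, tau_deoxy = tau_deoxy,
            tau_reoxy = tau_reoxy, h_amp = h_amp, t_peak = t_peak,
            noise_sd = noise_sd, drift_slope = drift_slope,
            pool_total = pool_total, baseline_offset = baseline_offset,
            seed = seed)
  if (any(c(p$k_sigmoid, p$tau_deoxy, p$tau_reoxy, p$t_peak) <= 0))
    stop("time constants and transition widths must be strictly positive")
  if (!is.null(p$cuff_pressure) && p$cuff_pressure < 0)
    stop("cuff_pressure must be non-negative")
  if (p$noise_sd < 0 || p$drift_slope < 0)
    stop("noise_sd and drift_slope must be non-negative")
  if (p$a_art <= 0 || p$a_ven < 0)
    stop("a_art must be positive, a_ven non-negative")
  if (p$baseline_tsi <= 0 || p$baseline_tsi >= 100)
    stop("baseline_tsi must lie strictly inside (0, 100)")
  if (p$pool_total <= 0) stop("pool_total must be positive")
  class(p) <- "sim_params"
  p
}

#' Occlusion completeness as a function of cuff pressure
#'
#' Smooth logistic interpolation between venous-only occlusion (completeness
#' 0) well below systolic pressure and complete arterial occlusion
#' (completeness 1) well above it:
#' `c = 1 / (1 + exp(-(P - SBP) / k))`, so `c = 0.5` exactly at `P = SBP`.
#'
#' @param cuff_pressure applied pressure, mmHg (vectorized).
#' @param sbp systolic blood pressure, mmHg.
#' @param k_sigmoid transition width, mmHg (> 0).
#' @return completeness in `(0, 1)`, monotone non-decreasing in
#'   `cuff_pressure`.
#' @examples
#' occlusion_completeness(116, 116, 10)        # 0.5
#' occlusion_completeness(166, 116, 10)        # ~0.9933
#' @export
occlusion_completeness <- function(cuff_pressure, sbp, k_sigmoid = 10) {
  if (k_sigmoid <= 0) stop("k_sigmoid must be strictly positive")
  1 / (1 + exp(-(cuff_pressure - sbp) / k_sigmoid))
}

#' Resolve a group pressure rule to a cuff pressure
#'
#' Rules are either absolute (a number, mmHg) or individualized relative to
#' the subject's SBP, written `"SBP+<delta>"` (e.g. `"SBP+50"`).
#'
#' @param rule numeric pressure or a `"SBP+delta"` string.
#' @param sbp the subject's systolic blood pressure, mmHg.
#' @return cuff pressure in mmHg.
#' @examples
#' resolve_cuff_pressure("SBP+50", 116)  # 166
#' @export
resolve_cuff_pressure <- function(rule, sbp) {
  if (is.numeric(rule)) return(rule)
  if (is.character(rule) && grepl("^\\s*SBP\\s*\\+\\s*[0-9.]+\\s*$", rule,
                                  ignore.case = TRUE)) {
    delta <- as.numeric(sub(".*\\+\\s*", "", rule))
    return(sbp + delta)
  }
  stop("unrecognized pressure rule: ", deparse(rule))
}

# single-peak overshoot shape, unit amplitude, peak 1 at x = 1
alpha_fun <- function(x) ifelse(x > 0, x * exp(1 - x), 0)

# Closed-form clean (noise- and drift-free) deviation model for one cycle.
# Returns scalar-safe vectorized functions of absolute time, valid anywhere
# (zero outside the cycle). Used both by the simulator and by the
# ground-truth oracle, which evaluates them with uniroot/optimize/integrate
# rather than through the extraction code path.
cycle_model <- function(pars, completeness, t0, t1, t2, ramp) {
  A <- pars$a_ven + completeness * pars$a_art
  D_end <- A * (1 - exp(-(t1 - t0) / pars$tau_deoxy))
  h_conc <- pars$h_amp * pars$pool_total / 100 * completeness
  hhb <- function(t) {
    u <- t - t0
    occ <- A * (1 - exp(-pmax(u, 0) / pars$tau_deoxy)) *
      pmin(pmax(u, 0) / ramp, 1)
    w <- pmax(t - t1 - ramp, 0)
    rep_ <- D_end * exp(-w / pars$tau_reoxy)
    ifelse(t < t0 | t >= t2, 0, ifelse(t < t1, occ, rep_))
  }
  base_hhb <- hhb
  over <- function(t) {
    w <- pmax(t - t1 - ramp, 0)
    ifelse(t >= t1 & t < t2, h_conc * alpha_fun(w / pars$t_peak), 0)
  }
  # arterial-inflow exchange: the overshoot moves hemoglobin from the
  # deoxygenated to the oxygenated pool, leaving total hemoglobin unchanged
  hhb <- function(t) base_hhb(t) - over(t)
  o2hb <- function(t) -base_hhb(t) + over(t)
  po0 <- pars$baseline_tsi / 100 * pars$pool_total
  ph0 <- pars$pool_total - po0
  tsi <- function(t) {
    o <- o2hb(t); h <- hhb(t)
    100 * (po0 + o) / (pars$pool_total + o + h) - pars$baseline_tsi
  }
  list(hhb = hhb, o2hb = o2hb, tsi = tsi,
       dhb = function(t) o2hb(t) - hhb(t),
       A = A, D_end = D_end, h_conc = h_conc)
}

#' Simulate one NIRS occlusion-reperfusion session
#'
#' Generates a full session on a uniform 10 Hz grid following `schedule`:
#' flat baseline, exponential deoxygenation during each occlusion with
#' amplitude `a_ven + c * a_art` (where `c` is the occlusion completeness for
#' the applied cuff pressure), mirrored O2Hb, exponential return to baseline
#' with a hyperemic overshoot on deflation, linear cuff inflation/deflation
#' ramps, per-channel Gaussian noise and linear drift. TSI is computed from
#' the absolute pools including noise and drift, so derived and simulated
#' channels stay consistent.
#'
#' @param params a [sim_params()] object with `cuff_pressure` set.
#' @param schedule a [build_schedule()] protocol.
#' @param sampling_rate sampling rate, Hz.
#' @return list with elements `recording` (a `nirs_recording`, raw/unfiltered)
#'   and `truth` (a data frame of per-cycle ground-truth model parameters:
#'   completeness, amplitudes, time constants, overshoot parameters, phase
#'   boundaries).
#' @export
simulate_session <- function(params, schedule = build_schedule(),
                             sampling_rate = 10) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(params$cuff_pressure))
    stop("params$cuff_pressure must be set (see resolve_cuff_pressure)")
  if (!is.null(params$seed)) set.seed(params$seed)
  ramp <- attr(schedule, "cuff_ramp_s")
  total <- attr(schedule, "total_s")
  dt <- 1 / sampling_rate
  tt <- seq(0, total - dt, by = dt)
  cyc <- schedule_cycles(schedule)
  cc <- occlusion_completeness(params$cuff_pressure, params$sbp,
                               params$k_sigmoid)
  o2 <- numeric(length(tt))
  hh <- numeric(length(tt))
  truth <- vector("list", nrow(cyc))
  for (i in seq_len(nrow(cyc))) {
    m <- cycle_model(params, cc, cyc$occl_start[i], cyc$occl_end[i],
                     cyc$reperf_end[i], ramp)
    idx <- tt >= cyc$occl_start[i] & tt < cyc$reperf_end[i]
    o2[idx] <- o2[idx] + m$o2hb(tt[idx])
    hh[idx] <- hh[idx] + m$hhb(tt[idx])
    truth[[i]] <- data.frame(
      cycle = i, completeness = cc, amp_hhb = m$A, amp_over_conc = m$h_conc,
      tau_deoxy = params$tau_deoxy, tau_reoxy = params$tau_reoxy,
      h_amp_tsi = params$h_amp * cc, t_peak = params$t_peak,
      occl_start = cyc$occl_start[i], occl_end = cyc$occl_end[i],
      reperf_end = cyc$reperf_end[i])
  }
  # drift and noise enter the raw channels; TSI inherits them via the pools
  drift_o <- runif(1, -params$drift_slope, params$drift_slope) * tt
  drift_h <- runif(1, -params$drift_slope, params$drift_slope) * tt
  eps_o <- rnorm(length(tt), 0, params$noise_sd)
  eps_h <- rnorm(length(tt), 0, params$noise_sd)
  o2_raw <- o2 + drift_o + eps_o + params$baseline_offset
  hh_raw <- hh + drift_h + eps_h + params$baseline_offset
  po0 <- params$baseline_tsi / 100 * params$pool_total
  ph0 <- params$pool_total - po0
  tsi <- compute_tsi(po0 + o2_raw, ph0 + hh_raw)
  rec <- nirs_recording(tt, o2_raw, hh_raw, tsi,
                        sampling_rate = sampling_rate, tsi_source = "device")
  rec$provenance <- sprintf(
    "simulate_session: cuff=%g sbp=%g completeness=%.4g noise_sd=%g",
    params$cuff_pressure, params$sbp, cc, params$noise_sd)
  list(recording = rec, truth = do.call(rbind, truth))
}

#' Default pressure-group specification
#'
#' Three groups: venous-only absolute 50 mmHg (n = 9), individualized
#' SBP + 50 mmHg (n = 14), and absolute 250 mmHg (n = 12).
#' @return named list of `list(rule, n)` entries.
#' @export
default_groups <- function() {
  list(G1 = list(rule = 50, n = 9),
       G2 = list(rule = "SBP+50", n = 14),
       G3 = list(rule = 250, n = 12))
}

#' Simulate a multi-group, two-session cohort
#'
#' Draws one SBP per subject from `Normal(sbp_mean, sbp_sd)`, resolves each
#' group's pressure rule, and simulates `sessions` independent sessions per
#' subject. Sessions differ by their noise/drift realizations and by a
#' per-subject-session random baseline offset on the concentration pools.
#'
#' @param group_specs named list of `list(rule, n)` (see [default_groups()]).
#' @param seed integer seed for the whole cohort, or `NULL`.
#' @param schedule protocol schedule.
#' @param params base [sim_params()]; `sbp` and `cuff_pressure` are
#'   overridden per subject.
#' @param sessions number of sessions per subject (default 2).
#' @param sbp_mean,sbp_sd cohort SBP distribution, mmHg (defaults 118, 9).
#' @param session_offset_sd SD of the between-session baseline offset
#'   (device units).
#' @return an object of class `vot_cohort`: list with `manifest` (subject_id,
#'   group, session, sbp, cuff_pressure, file), `recordings` (named list of
#'   `nirs_recording`), `truth` (per subject x session x cycle ground truth),
#'   `schedule`, `params`.
#' @export
simulate_cohort <- function(group_specs = default_groups(), seed = NULL,
                            schedule = build_schedule(),
                            params = sim_params(), sessions = 2,
                            sbp_mean = 118, sbp_sd = 9,
                            session_offset_sd = 1) {
  if (length(group_specs) == 0L) stop("group_specs must name at least one group")
  for (g in names(group_specs))
    if (is.null(group_specs[[g]]$n) || group_specs[[g]]$n < 1)
      stop("group ", g, " must have n >= 1")
  if (!is.null(seed)) set.seed(seed)
  manifest <- list(); recs <- list(); truth <- list()
  sid <- 0L
  for (g in names(group_specs)) {
    spec <- group_specs[[g]]
    for (k in seq_len(spec$n)) {
      sid <- sid + 1L
      subject <- sprintf("S%02d", sid)
      sbp <- rnorm(1, sbp_mean, sbp_sd)
      cuff <- resolve_cuff_pressure(spec$rule, sbp)
      for (s in seq_len(sessions)) {
        p <- params
        p$sbp <- sbp
        p$cuff_pressure <- cuff
        p$baseline_offset <- rnorm(1, 0, session_offset_sd)
        p$seed <- NULL
        sim <- simulate_session(p, schedule)
        key <- sprintf("%s_S%d", subject, s)
        recs[[key]] <- sim$recording
        manifest[[key]] <- data.frame(
          subject_id = subject, group = g, session = paste0("S", s),
          sbp = sbp, cuff_pressure = cuff,
          file = paste0(key, ".csv"), stringsAsFactors = FALSE)
        tr <- sim$truth
        tr$subject_id <- subject; tr$group <- g
        tr$session <- paste0("S", s)
        truth[[key]] <- tr
      }
    }
  }
  structure(list(manifest = do.call(rbind, c(manifest,
                                             list(make.row.names = FALSE))),
                 recordings = recs,
                 truth = do.call(rbind, c(truth,
                                          list(make.row.names = FALSE))),
                 schedule = schedule, params = params),
            class = "vot_cohort")
}

#' @export
print.vot_cohort <- function(x, ...) {
  cat("Synthetic VOT cohort:", nrow(x$manifest), "recordings,",
      length(unique(x$manifest$subject_id)), "subjects,",
      length(unique(x$manifest$group)), "groups\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes one recording CSV per subject-session, a `manifest.csv` and a
#' `ground_truth.csv`, all with `#`-prefixed provenance headers.
#'
#' @param cohort a `vot_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vot_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(cohort$recordings))
    write_nirs_csv(cohort$recordings[[key]],
                   file.path(dir, paste0(key, ".csv")))
  write_table_csv(cohort$manifest, file.path(dir, "manifest.csv"),
                  "cohort manifest")
  write_table_csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                  "simulator ground truth (synthetic)")
  invisible(dir)
}
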