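#' Build a vascular occlusion test protocol schedule
#'
#' A schedule is an ordered set of contiguous, non-overlapping, half-open
#' phases `[t_start, t_end)` covering the recording from time zero. The
#' default reproduces the standard three-cycle protocol: a 15-min resting
#' baseline, then three 7-min occlusions interleaved with reperfusion phases
#' of 10, 10 and 20 min, for a total of 4560 s. Cuff inflation/deflation is
#' not instantaneous; `cuff_ramp_s` records the assumed linear ramp duration
#' used when windows are offset for event detection.
#'
#' @param baseline_s baseline duration in seconds (default 900).
#' @param occlusion_s duration of each occlusion in seconds (default 420).
#' @param reperfusion_s vector of reperfusion durations in seconds, one per
#'   occlusion (default `c(600, 600, 1200)`).
#' @param cuff_ramp_s cuff inflation/deflation ramp duration in seconds
#'   (default 6, within the 5-8 s range typical of manual sphygmomanometers).
#' @return an object of class `vot_schedule`: a data frame with columns
#'   `label`, `t_start`, `t_end` and attributes `cuff_ramp_s`, `total_s`.
#' @examples
#' sch <- build_schedule()
#' nrow(sch)              # 7 phases
#' attr(sch, "total_s")   # 4560
#' @export
build_schedule <- function(baseline_s = 900, occlusion_s = 420,
                           reperfusion_s = c(600, 600, 1200),
                           cuff_ramp_s = 6) {
  durs <- c(baseline_s, if (length(reperfusion_s))
    as.vector(rbind(rep(occlusion_s, length(reperfusion_s)), reperfusion_s)))
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("all phase durations must be positive and finite")
  if (cuff_ramp_s < 0) stop("cuff_ramp_s must be non-negative")
  ncyc <- length(reperfusion_s)
  labels <- c("baseline",
              if (ncyc) as.vector(rbind(paste0("O", seq_len(ncyc)),
                                        paste0("R", seq_len(ncyc)))))
  ends <- cumsum(durs)
  sch <- data.frame(label = labels,
                    t_start = c(0, ends[-length(ends)]),
                    t_end = ends,
                    stringsAsFactors = FALSE)
  validate_schedule(sch)
  structure(sch, cuff_ramp_s = cuff_ramp_s, total_s = ends[length(ends)],
            class = c("vot_schedule", "data.frame"))
}

#' Assemble a schedule from an explicit phase table
#'
#' Accepts arbitrary phase layouts (e.g. a baseline-only recording) for reuse
#' outside the default protocol. Phases must be contiguous from 0 and
#' non-overlapping.
#'
#' @param phases data frame with columns `label`, `t_start`, `t_end`.
#' @param cuff_ramp_s see [build_schedule()].
#' @return a `vot_schedule`.
#' @export
as_schedule <- function(phases, cuff_ramp_s = 6) {
  stopifnot(is.data.frame(phases),
            all(c("label", "t_start", "t_end") %in% names(phases)))
  phases <- phases[order(phases$t_start), , drop = FALSE]
  validate_schedule(phases)
  structure(as.data.frame(phases, stringsAsFactors = FALSE),
            cuff_ramp_s = cuff_ramp_s,
            total_s = phases$t_end[nrow(phases)],
            class = c("vot_schedule", "data.frame"))
}

validate_schedule <- function(sch) {
  if (nrow(sch) == 0L) stop("schedule has no phases")
  if (any(sch$t_end <= sch$t_start)) stop("phase with non-positive duration")
  if (sch$t_start[1] != 0) stop("schedule must start at t = 0")
  if (nrow(sch) > 1L) {
    gaps <- sch$t_start[-1] - sch$t_end[-nrow(sch)]
    if (any(abs(gaps) > 1e-9))
      stop("phases must be contiguous and non-overlapping")
  }
  invisible(sch)
}

#' Occlusion/reperfusion cycle windows of a schedule
#'
#' @param schedule a `vot_schedule`.
#' @return data frame with one row per occlusion-reperfusion cycle:
#'   `cycle`, `occl_start`, `occl_end`, `reperf_start`, `reperf_end`.
#' @export
schedule_cycles <- function(schedule) {
  occ <- schedule[grepl("^O[0-9]+$", schedule$label), , drop = FALSE]
  rep_ <- schedule[grepl("^R[0-9]+$", schedule$label), , drop = FALSE]
  if (nrow(occ) != nrow(rep_))
    stop("schedule has unmatched occlusion/reperfusion phases")
  data.frame(cycle = seq_len(nrow(occ)),
             occl_start = occ$t_start, occl_end = occ$t_end,
             reperf_start = rep_$t_start, reperf_end = rep_$t_end)
}

#' @export
print.vot_schedule <- function(x, ...) {
  cat("Vascular occlusion test schedule:", nrow(x), "phases,",
      attr(x, "total_s"), "s total, cuff ramp", attr(x, "cuff_ramp_s"), "s\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
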