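#' Construct a NIRS recording object
#'
#' A `nirs_recording` holds uniformly sampled oxy-/deoxyhemoglobin
#' concentration-change channels (`o2hb`, `hhb`; device units) and a tissue
#' saturation index channel (`tsi`, percent), on a common strictly increasing
#' time grid. The hemoglobin difference channel `dhb = o2hb - hhb` is carried
#' alongside once computed. Normalization state is tracked so that a recording
#' cannot be baseline-normalized twice.
#'
#' @param time numeric vector of sample times in seconds (uniform grid).
#' @param o2hb,hhb,tsi numeric channel vectors, same length as `time`.
#' @param sampling_rate sampling rate in Hz (default 10).
#' @param normalized logical; whether channels are expressed as deviations
#'   from a baseline-window mean.
#' @param baseline_window the `[t_start, t_end)` window used for
#'   normalization, or `NULL`.
#' @param tsi_source `"device"` if the TSI channel came from the instrument,
#'   `"derived"` if computed from the concentration channels.
#' @param dhb optional hemoglobin difference channel.
#' @return an object of class `nirs_recording`.
#' @export
nirs_recording <- function(time, o2hb, hhb, tsi, sampling_rate = 10,
                           normalized = FALSE, baseline_window = NULL,
                           tsi_source = "device", dhb = NULL) {
  n <- length(time)
  chans <- list(o2hb = o2hb, hhb = hhb, tsi = tsi)
  if (!is.null(dhb)) chans$dhb <- dhb
  for (nm in names(chans)) {
    if (length(chans[[nm]]) != n)
      stop("channel '", nm, "' length differs from time vector")
    if (!is.numeric(chans[[nm]]))
      stop("channel '", nm, "' is not numeric")
  }
  if (n < 2L) stop("a recording needs at least two samples")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(abs(dt - 1 / sampling_rate)) > 1e-6)
    stop("time grid is not uniform at the declared sampling rate")
  rec <- list(data = do.call(data.frame, c(list(time = time), chans)),
              sampling_rate = sampling_rate,
              normalized = isTRUE(normalized),
              baseline_window = baseline_window,
              tsi_source = tsi_source,
              provenance = character())
  class(rec) <- "nirs_recording"
  rec
}

#' Channel names of a recording
#' @param rec a `nirs_recording`.
#' @return character vector of channel names (excludes `time`).
#' @export
channels <- function(rec) setdiff(names(rec$data), "time")

#' @export
print.nirs_recording <- function(x, ...) {
  d <- x$data
  cat(sprintf("NIRS recording: %d samples @ %g Hz (%.1f s), channels: %s\n",
              nrow(d), x$sampling_rate, d$time[nrow(d)] - d$time[1],
              paste(channels(x), collapse = ", ")))
  cat(sprintf("  normalized: %s%s; TSI source: %s\n",
              x$normalized,
              if (x$normalized)
                sprintf(" (baseline window [%g, %g) s)",
                        x$baseline_window[1], x$baseline_window[2]) else "",
              x$tsi_source))
  invisible(x)
}

#' @export
as.data.frame.nirs_recording <- function(x, ...) x$data

#' Tissue saturation index from hemoglobin pools
#'
#' TSI expresses the balance between oxygen supply and consumption as the
#' oxygenated fraction of total hemoglobin:
#' `100 * o2hb / (o2hb + hhb)` percent. The inputs must be absolute
#' (non-negative) pool values, not baseline-subtracted changes. Samples with
#' a non-positive denominator are returned as `NA` with a warning rather than
#' an error, so isolated bad samples do not abort a pipeline.
#'
#' @param o2hb,hhb absolute hemoglobin pool values, equal length.
#' @return TSI in percent, in `[0, 100]` where inputs are non-negative.
#' @examples
#' compute_tsi(30, 10)  # 75
#' @export
compute_tsi <- function(o2hb, hhb) {
  if (length(o2hb) != length(hhb)) stop("o2hb and hhb lengths differ")
  den <- o2hb + hhb
  bad <- !is.na(den) & den <= 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) with non-positive total pool flagged as NA")
    den[bad] <- NA_real_
  }
  100 * o2hb / den
}

#' Hemoglobin difference channel
#'
#' `dhb = o2hb - hhb`, an index of oxygenated blood. Being linear, it
#' commutes with baseline normalization and filtering.
#'
#' @param o2hb,hhb channel vectors of equal length.
#' @return elementwise difference.
#' @export
compute_delta_hb <- function(o2hb, hhb) {
  if (length(o2hb) != length(hhb)) stop("o2hb and hhb lengths differ")
  o2hb - hhb
}
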