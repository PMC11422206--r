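#' @importFrom stats approx lm coef rnorm runif sd var median shapiro.test
#'   kruskal.test t.test pnorm pf aov setNames complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linear interpolation of the time at which a series crosses a level
#'
#' Scans consecutive sample pairs for a bracketing of `level` and returns the
#' linearly interpolated crossing time. Direction of the scan is controlled by
#' `from`: `"left"` returns the first crossing at or after the start of the
#' vector, `"right"` the last one.
#'
#' @param time numeric vector of sample times (strictly increasing).
#' @param y numeric vector, same length as `time`.
#' @param level the value whose crossing is sought.
#' @param from `"left"` or `"right"`.
#' @return crossing time in the units of `time`, or `NA_real_` if the series
#'   never brackets `level`.
#' @keywords internal
interp_crossing <- function(time, y, level, from = c("left", "right")) {
  from <- match.arg(from)
  d <- y - level
  hit <- which(d == 0)
  sgn <- d[-length(d)] * d[-1]
  brk <- which(sgn < 0)
  cand <- c(time[hit], time[brk] + (time[brk + 1] - time[brk]) *
              (level - y[brk]) / (y[brk + 1] - y[brk]))
  if (length(cand) == 0L) return(NA_real_)
  if (from == "left") min(cand) else max(cand)
}

#' Trapezoidal integral of a sampled series between two (possibly off-grid)
#' time bounds
#'
#' Interior samples are integrated with [pracma::trapz()]; partial intervals
#' at the bounds use linearly interpolated endpoint values, so the result is
#' exact for piecewise-linear signals.
#'
#' @param time,y sampled series (uniform or not, strictly increasing time).
#' @param t0,t1 integration bounds, `t0 <= t1`, inside the time range.
#' @return the signed integral in units of `y * time`.
#' @keywords internal
auc_between <- function(time, y, t0, t1) {
  if (t1 < t0) stop("inverted integration bounds (t0 > t1)")
  if (t0 < time[1] || t1 > time[length(time)])
    stop("integration bounds outside the sampled record")
  if (t1 == t0) return(0)
  inside <- time >= t0 & time <= t1
  if (sum(inside) < 2L) {
    y0 <- approx(time, y, xout = c(t0, t1))$y
    return(mean(y0) * (t1 - t0))
  }
  tt <- time[inside]
  yy <- y[inside]
  total <- pracma::trapz(tt, yy)
  if (tt[1] > t0) {
    y0 <- approx(time, y, xout = t0)$y
    total <- total + (y0 + yy[1]) / 2 * (tt[1] - t0)
  }
  nlast <- length(tt)
  if (tt[nlast] < t1) {
    y1 <- approx(time, y, xout = t1)$y
    total <- total + (yy[nlast] + y1) / 2 * (t1 - tt[nlast])
  }
  total
}

# indices of samples falling in the half-open window [t0, t1)
window_idx <- function(time, t0, t1) which(time >= t0 & time < t1)

# write a data frame as CSV with '#'-prefixed provenance header lines
write_table_csv <- function(df, path, what, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# nirsvot: ", what),
               if (length(extra)) paste0("# ", extra)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_table_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
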