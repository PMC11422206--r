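#' Read a NIRS recording from delimited text
#'
#' Reads one subject-session recording from a CSV/TSV file. Lines starting
#' with `#` are treated as provenance comments and skipped. Column names are
#' mapped through `column_map`; a missing `tsi` entry triggers derivation of
#' the TSI channel from the concentration columns (logged via message),
#' because spatially resolved device TSI cannot be reconstructed from
#' concentration changes alone and is preferred when present.
#'
#' Non-uniform time grids are resampled to the declared rate by linear
#' interpolation with a warning; gaps of at most `max_gap_s` are bridged by
#' that interpolation, longer gaps fail the recording since zero-phase
#' filtering requires a uniform grid.
#'
#' @param path file path.
#' @param column_map named character vector mapping recording fields to file
#'   columns; must name `time`, `o2hb`, `hhb` and optionally `tsi`.
#' @param sampling_rate declared sampling rate in Hz.
#' @param sep field separator (default `,`).
#' @param max_gap_s longest tolerated gap in seconds (default 0.5).
#' @return a `nirs_recording`.
#' @export
read_nirs_csv <- function(path,
                          column_map = c(time = "time_s", o2hb = "o2hb",
                                         hhb = "hhb", tsi = "tsi"),
                          sampling_rate = 10, sep = ",", max_gap_s = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, sep = sep, comment.char = "#",
                 stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty recording file: ", path)
  need <- c("time", "o2hb", "hhb")
  for (f in need) {
    col <- column_map[[f]]
    if (is.null(col) || !col %in% names(df))
      stop("column '", column_map[[f]] %||% f, "' (field ", f,
           ") missing in ", path)
  }
  get_num <- function(field) {
    col <- column_map[[field]]
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (anyNA(vn) & !anyNA(v))
        stop("non-numeric values in column '", col, "' of ", path,
             " (first bad row: ", which(is.na(vn))[1], ")")
      v <- vn
    }
    v
  }
  time <- get_num("time")
  o2hb <- get_num("o2hb")
  hhb <- get_num("hhb")
  has_tsi <- !is.null(column_map[["tsi"]]) &&
    column_map[["tsi"]] %in% names(df)
  tsi <- if (has_tsi) get_num("tsi") else NULL

  dt <- 1 / sampling_rate
  if (length(time) < 2L) stop("recording too short: ", path)
  gaps <- diff(time)
  if (any(gaps <= 0)) stop("time column not strictly increasing in ", path)
  if (any(gaps > max_gap_s + 1e-9))
    stop("gap of ", signif(max(gaps), 3), " s exceeds max_gap_s in ", path)
  uniform <- max(abs(gaps - dt)) <= 1e-6
  if (!uniform) {
    warning("non-uniform time grid in ", basename(path),
            "; resampling to ", sampling_rate, " Hz by linear interpolation")
    grid <- seq(time[1], time[length(time)], by = dt)
    o2hb <- approx(time, o2hb, xout = grid)$y
    hhb <- approx(time, hhb, xout = grid)$y
    if (has_tsi) tsi <- approx(time, tsi, xout = grid)$y
    time <- grid
  }
  if (!has_tsi) {
    message("no device TSI column in ", basename(path),
            "; deriving TSI from concentration channels")
    tsi <- compute_tsi(o2hb, hhb)
  }
  rec <- nirs_recording(time, o2hb, hhb, tsi, sampling_rate = sampling_rate,
                        tsi_source = if (has_tsi) "device" else "derived")
  rec$provenance <- paste0("source: ", basename(path))
  rec
}

#' Write a NIRS recording as CSV with provenance header
#'
#' Provenance lines (`#`-prefixed) record the normalization state, filter
#' settings and any upstream processing, so output files are self-describing
#' and round-trip through [read_nirs_csv()].
#'
#' @param rec a `nirs_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nirs_csv <- function(rec, path) {
  stopifnot(inherits(rec, "nirs_recording"))
  hdr <- c(paste0("# nirsvot recording; sampling_rate_hz=", rec$sampling_rate),
           paste0("# normalized=", rec$normalized,
                  if (rec$normalized)
                    sprintf("; baseline_window=[%g,%g)",
                            rec$baseline_window[1], rec$baseline_window[2])
                  else ""),
           paste0("# tsi_source=", rec$tsi_source),
           if (length(rec$provenance)) paste0("# ", rec$provenance))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  d <- rec$data
  names(d)[names(d) == "time"] <- "time_s"
  # 17 significant digits so doubles round-trip bitwise through the reader
  d[] <- lapply(d, function(v) sprintf("%.17g", v))
  write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
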