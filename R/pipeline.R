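#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one validated list:
#' protocol timing, filter design, baseline window, detection thresholds,
#' statistical alpha and the RNG seed. Values can be loaded from a YAML file
#' and overridden by arguments.
#'
#' @param file optional YAML file with any subset of the fields.
#' @param ... overrides (same names as the defaults).
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(file = NULL, ...) {
  cfg <- list(
    sampling_rate = 10,
    filter_order = 10,
    cutoff_hz = 0.8,
    baseline_window = c(150, 750),
    event_threshold = 0.10,
    decay_frac = 0.63,
    spike_horizon_s = 120,
    alpha = 0.05,
    seed = NULL,
    schedule = list(baseline_s = 900, occlusion_s = 420,
                    reperfusion_s = c(600, 600, 1200), cuff_ramp_s = 6),
    groups = NULL,       # NULL -> default_groups()
    sim = list(),        # overrides for sim_params()
    input_dir = NULL,
    output_dir = "nirsvot_out")
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    for (nm in names(y)) cfg[[nm]] <- y[[nm]]
  }
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  if (cfg$event_threshold <= 0 || cfg$event_threshold >= 1 ||
      cfg$decay_frac <= 0 || cfg$decay_frac >= 1)
    stop("event_threshold and decay_frac must lie in (0, 1)")
  if (cfg$cutoff_hz >= cfg$sampling_rate / 2)
    stop("cutoff_hz must be below the Nyquist frequency")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  class(cfg) <- "pipeline_config"
  cfg
}

config_schedule <- function(cfg) {
  do.call(build_schedule, cfg$schedule)
}

config_groups <- function(cfg) {
  if (is.null(cfg$groups)) return(default_groups())
  lapply(cfg$groups, function(g) list(rule = g$rule, n = g$n))
}

#' Simulate a cohort and write it to disk
#'
#' Deterministic under a fixed seed: the manifest, one recording CSV per
#' subject-session and the ground-truth table are written to
#' `cfg$output_dir`.
#'
#' @param cfg a [pipeline_config()].
#' @return the `vot_cohort`, invisibly.
#' @export
run_simulate <- function(cfg = pipeline_config()) {
  schedule <- config_schedule(cfg)
  params <- do.call(sim_params, cfg$sim)
  cohort <- simulate_cohort(config_groups(cfg), seed = cfg$seed,
                            schedule = schedule, params = params)
  write_cohort(cohort, cfg$output_dir)
  invisible(cohort)
}

# filter -> normalize -> segment -> extract -> average, for one recording
extract_session_summary <- function(rec, cfg, schedule = config_schedule(cfg)) {
  rec <- lowpass_zero_phase(rec, cfg$filter_order, cfg$cutoff_hz)
  rec <- normalize_to_baseline(rec, cfg$baseline_window)
  ext <- extract_cycle_features(rec, schedule,
                                threshold = cfg$event_threshold,
                                decay_frac = cfg$decay_frac,
                                spike_horizon_s = cfg$spike_horizon_s)
  avg <- average_cycles(ext$features)
  list(summary = avg, cycles = ext$features, marks = ext$marks)
}

#' Extract session summaries for a whole cohort
#'
#' Runs the fixed stage order (low-pass filter, baseline normalization,
#' segmentation, per-cycle features, cycle averaging) on every recording of
#' an in-memory cohort or of a directory written by [run_simulate()].
#' Unreadable files are skipped with a message; an empty result is an error.
#'
#' @param x a `vot_cohort` or a directory containing `manifest.csv` and the
#'   recording CSVs.
#' @param cfg a [pipeline_config()].
#' @return data frame of class `session_summary`: one row per subject x
#'   session (`subject_id`, `group`, `session`, `sbp`, `cuff_pressure`, one
#'   column per parameter).
#' @export
run_extract <- function(x, cfg = pipeline_config()) {
  schedule <- config_schedule(cfg)
  if (inherits(x, "vot_cohort")) {
    manifest <- x$manifest
    get_rec <- function(key, row) x$recordings[[key]]
  } else {
    mp <- file.path(x, "manifest.csv")
    if (!file.exists(mp)) stop("no manifest.csv in ", x)
    manifest <- read_table_csv(mp)
    get_rec <- function(key, row) {
      tryCatch(read_nirs_csv(file.path(x, row$file),
                             sampling_rate = cfg$sampling_rate),
               error = function(e) {
                 message("skipping ", row$file, ": ", conditionMessage(e))
                 NULL
               })
    }
  }
  rows <- list()
  for (j in seq_len(nrow(manifest))) {
    row <- manifest[j, ]
    key <- sprintf("%s_%s", row$subject_id, row$session)
    rec <- get_rec(key, row)
    if (is.null(rec)) next
    out <- extract_session_summary(rec, cfg, schedule)
    rows[[key]] <- cbind(row[c("subject_id", "group", "session",
                               "sbp", "cuff_pressure")],
                         out$summary, row.names = NULL)
  }
  if (length(rows) == 0L) stop("no readable recordings; nothing extracted")
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(res) <- c("session_summary", "data.frame")
  res
}

#' Write a session summary table as CSV
#' @param summary a `session_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_session_summary <- function(summary, path) {
  write_table_csv(as.data.frame(summary), path,
                  "session summary (one row per subject x session)")
}

#' Group statistics for every extracted parameter
#'
#' Runs [compare_groups()] per parameter over a session-summary table and
#' assembles the results in one long table mirroring the standard report
#' layout. Parameters missing for all subjects are skipped with a message.
#'
#' @param summary a `session_summary` (or equivalent data frame).
#' @param cfg a [pipeline_config()].
#' @param parameters parameter columns to analyze; default all.
#' @return list with `table` (data frame: Variable, Session, A, B, means,
#'   SDs, corrected p, effect size and kind), `detail` (per-parameter
#'   `group_comparison` objects).
#' @export
run_stats <- function(summary, cfg = pipeline_config(), parameters = NULL) {
  meta <- c("subject_id", "group", "session", "sbp", "cuff_pressure")
  parameters <- parameters %||% setdiff(names(summary), meta)
  if (length(unique(summary$group)) < 2L)
    stop("statistics require at least 2 groups")
  detail <- list(); tabs <- list()
  for (p in parameters) {
    long <- data.frame(subject_id = summary$subject_id,
                       group = summary$group, session = summary$session,
                       value = summary[[p]])
    if (all(is.na(long$value))) {
      message("parameter skipped (all missing): ", p)
      next
    }
    cmp <- compare_groups(long, alpha = cfg$alpha)
    detail[[p]] <- cmp
    pw <- cmp$pairwise
    tabs[[p]] <- data.frame(
      Variable = p, Session = pw$session, A = pw$A, B = pw$B,
      A_mean = pw$mean_A, A_sd = pw$sd_A, B_mean = pw$mean_B,
      B_sd = pw$sd_B, p_corrected = pw$p_corrected,
      effect_size = pw$effect_size, effect_kind = pw$effect_kind,
      route = cmp$route, stringsAsFactors = FALSE)
  }
  if (length(tabs) == 0L) stop("no parameter could be analyzed")
  list(table = do.call(rbind, c(tabs, list(make.row.names = FALSE))),
       detail = detail)
}

#' Plain-text report of significant pairwise differences
#'
#' @param stats result of [run_stats()].
#' @param alpha significance threshold.
#' @return character vector of report lines, invisibly printed.
#' @export
run_report <- function(stats, alpha = 0.05) {
  tb <- stats$table
  sig <- tb[!is.na(tb$p_corrected) & tb$p_corrected < alpha, ]
  lines <- c(sprintf("Significant pairwise differences at alpha = %g:", alpha),
             if (nrow(sig) == 0L) "  (none)" else
               sprintf("  %s [%s] %s vs %s: p = %.4g, %s = %.3f",
                       sig$Variable, sig$Session, sig$A, sig$B,
                       sig$p_corrected, sig$effect_kind, sig$effect_size))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Cohort accounting after exclusions
#'
#' Number of participants retained after subtracting exclusion counts from
#' the enrolled total (e.g. technical failures and signal-quality
#' exclusions such as a tissue saturation index hitting 0% or prolonged
#' degraded signal).
#'
#' @param enrolled enrolled participants.
#' @param exclusions numeric vector of exclusion counts.
#' @return included n.
#' @examples
#' apply_exclusions(46, c(technical = 4, signal_quality = 7))  # 35
#' @export
apply_exclusions <- function(enrolled, exclusions = numeric()) {
  if (enrolled < 0 || any(exclusions < 0)) stop("counts must be non-negative")
  n <- enrolled - sum(exclusions)
  if (n < 0) stop("exclusions exceed enrollment")
  n
}
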