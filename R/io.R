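# Readers/writers for the pipeline's CSV dialects. All files carry a single
# header row; timestamps are ISO-8601 UTC with milliseconds; placements use
# the fixed vocabulary. data.table handles the bulk I/O (raw signals are
# tens of thousands of rows per session).

EPOCH <- "2020-01-06 08:00:00" # arbitrary fixed cohort epoch (UTC)

#' Write one raw accelerometer session as CSV
#'
#' Columns: `timestamp` (ISO-8601 with milliseconds), `accel_x`, `accel_y`,
#' `accel_z` (g).
#'
#' @param session a `recording_session`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(session, path) {
  n <- nrow(session$samples)
  t <- session$start_time + (seq_len(n) - 1) / session$sample_rate
  dt <- data.table::data.table(
    timestamp = iso8601(t, EPOCH),
    accel_x = session$samples[, 1],
    accel_y = session$samples[, 2],
    accel_z = session$samples[, 3])
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a raw accelerometer CSV
#'
#' Accepts the package's own dialect by default; `column_map` remaps header
#' names for ActiGraph-style raw exports (`skip` drops preamble rows).
#'
#' @param path input file.
#' @param participant_id,activity,placement session identity (not stored in
#'   the raw file).
#' @param column_map named character vector mapping the dialect's column
#'   names onto `timestamp`, `accel_x`, `accel_y`, `accel_z`.
#' @param skip header rows to skip before the column header.
#' @return a `recording_session` (sample rate inferred from timestamps).
#' @export
read_session_csv <- function(path, participant_id = NA_character_,
                             activity = NA_character_,
                             placement = NA_character_,
                             column_map = c(timestamp = "timestamp",
                                            accel_x = "accel_x",
                                            accel_y = "accel_y",
                                            accel_z = "accel_z"),
                             skip = 0) {
  dt <- data.table::fread(path, skip = skip)
  missing <- setdiff(unname(column_map), names(dt))
  if (length(missing))
    stop_arg("columns missing from ", path, ": ",
             paste(missing, collapse = ", "))
  t <- from_iso8601(dt[[column_map[["timestamp"]]]], EPOCH)
  n <- length(t)
  rate <- round(1 / stats::median(diff(t)))
  samples <- cbind(x = dt[[column_map[["accel_x"]]]],
                   y = dt[[column_map[["accel_y"]]]],
                   z = dt[[column_map[["accel_z"]]]])
  structure(list(participant_id = participant_id, activity_name = activity,
                 placement = placement, sample_rate = rate,
                 samples = samples, start_time = t[1],
                 stop_time = t[1] + n / rate),
            class = "recording_session")
}

#' Write / read the activity log CSV
#'
#' Columns: `participant_id`, `activity`, `category`, `start`, `stop`
#' (ISO-8601).
#' @param log activity-log data.frame (seconds-based `start`/`stop`).
#' @param path file path.
#' @return `path` / the log with numeric `start`, `stop` in seconds.
#' @export
write_activity_log_csv <- function(log, path) {
  out <- data.frame(participant_id = log$participant_id,
                    activity = log$activity, category = log$category,
                    start = iso8601(log$start, EPOCH),
                    stop = iso8601(log$stop, EPOCH))
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_activity_log_csv
#' @export
read_activity_log_csv <- function(path) {
  dt <- as.data.frame(data.table::fread(path))
  dt$start <- from_iso8601(dt$start, EPOCH)
  dt$stop <- from_iso8601(dt$stop, EPOCH)
  dt
}

#' Write / read the VO2 CSV
#'
#' Long format, one row per breath: `participant_id`, `activity`,
#' `t_seconds`, `vo2_ml_min_kg`.
#' @param traces list of `vo2_trace` (e.g. `cohort$vo2`).
#' @param path file path.
#' @return `path` / a list of `vo2_trace`.
#' @export
write_vo2_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr)
    data.frame(participant_id = tr$participant_id,
               activity = tr$activity_name,
               t_seconds = tr$breath_times,
               vo2_ml_min_kg = tr$vo2_values))
  data.table::fwrite(do.call(rbind, rows), path)
  invisible(path)
}

#' @rdname write_vo2_csv
#' @export
read_vo2_csv <- function(path) {
  dt <- as.data.frame(data.table::fread(path))
  keys <- unique(dt[, c("participant_id", "activity")])
  traces <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- dt[dt$participant_id == keys$participant_id[i] &
                dt$activity == keys$activity[i], ]
    structure(list(participant_id = keys$participant_id[i],
                   activity_name = keys$activity[i],
                   breath_times = sub$t_seconds,
                   vo2_values = sub$vo2_ml_min_kg,
                   true_met = NA_real_),
              class = "vo2_trace")
  })
  names(traces) <- paste(keys$participant_id, keys$activity, sep = "|")
  traces
}

#' Write / read a feature table CSV
#'
#' Stable column order: identifiers and labels first, then the 15 features
#' per placement grouped in the fixed order ankle, upper_arm, hip, thigh,
#' wrist.
#' @param features a `feature_table`.
#' @param path file path.
#' @return `path` / a `feature_table`.
#' @export
write_feature_csv <- function(features, path) {
  id_cols <- intersect(c("participant_id", "activity", "category",
                         "is_sedentary", "is_locomotion", "is_lifestyle",
                         "window_index", "window_start", "met"),
                       names(features))
  feat_cols <- unlist(lapply(names(PLACEMENTS), function(pl) {
    cols <- paste(pl, FEATURE_NAMES, sep = "_")
    cols[cols %in% names(features)]
  }))
  data.table::fwrite(features[, c(id_cols, feat_cols)], path)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  out <- as.data.frame(data.table::fread(path))
  class(out) <- c("feature_table", class(out))
  out
}
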