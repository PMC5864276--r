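# CSV readers/writers for the session interchange format.
#
# Dialects (UTF-8, header row required):
#   trials.csv   trial_id,cue_type,cue_onset_s,cue_offset_s,reward_time_s
#                (empty reward_time_s = no reward on that trial)
#   spikes.csv   unit_id,spike_time_s
#   entries.csv  port_entry_time_s
#   tracking.csv frame,t_s,x_cm,y_cm,missing   (missing: 0/1)
# session.yaml carries task_kind, session_duration and port coordinates.

read_csv_checked <- function(path, required_cols, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
  )
  miss <- setdiff(required_cols, names(df))
  if (length(miss))
    stop("parse error in ", path, ": missing columns ",
         paste(miss, collapse = ", "))
  for (col in numeric_cols) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !(is.na(raw) | raw == "" | raw == "NA"))
    if (length(bad))
      stop("parse error in ", path, " line ", bad[1] + 1,
           ": non-numeric value in column ", col)
    df[[col]] <- val
  }
  df
}

#' Load a session from its CSV files
#'
#' @param trials_file,spikes_file,entries_file paths to the trial, spike and
#'   port-entry tables.
#' @param tracking_file optional path to the tracking trace.
#' @param task_kind "pavlovian" or "instrumental".
#' @param port_xy reward-port coordinates (cm), required with tracking.
#' @param session_duration seconds; inferred from the data when omitted.
#' @return A validated `vp_session`.
#' @seealso [save_session()] for the inverse, [load_session_dir()] to read a
#'   directory written by `save_session`.
#' @export
load_session <- function(trials_file, spikes_file, entries_file,
                         tracking_file = NULL, task_kind,
                         port_xy = NULL, session_duration = NULL) {
  tr <- read_csv_checked(trials_file,
    c("trial_id", "cue_type", "cue_onset_s", "cue_offset_s", "reward_time_s"),
    c("cue_onset_s", "cue_offset_s", "reward_time_s"))
  trials <- data.frame(
    trial_id = as.integer(tr$trial_id),
    cue_type = tr$cue_type,
    cue_onset = tr$cue_onset_s,
    cue_offset = tr$cue_offset_s,
    reward_time = tr$reward_time_s,
    stringsAsFactors = FALSE
  )
  sp <- read_csv_checked(spikes_file, c("unit_id", "spike_time_s"),
                         "spike_time_s")
  if (any(sp$spike_time_s < 0))
    stop_validation("invariant violated: spike times >= 0 (", spikes_file, ")")
  units <- split(sp$spike_time_s, sp$unit_id)
  units <- lapply(units, sort)
  en <- read_csv_checked(entries_file, "port_entry_time_s", "port_entry_time_s")
  tracking <- NULL
  if (!is.null(tracking_file)) {
    tracking <- read_csv_checked(tracking_file,
      c("frame", "t_s", "x_cm", "y_cm", "missing"),
      c("t_s", "x_cm", "y_cm"))
    tracking$missing <- as.integer(tracking$missing)
  }
  vp_session(trials, units, en$port_entry_time_s, task_kind,
             tracking = tracking, port_xy = port_xy,
             session_duration = session_duration)
}

#' Save a session as CSV files plus a YAML sidecar
#'
#' Writes `trials.csv`, `spikes.csv`, `entries.csv`, optionally
#' `tracking.csv`, and `session.yaml` into `dir`.
#'
#' @param session a `vp_session`.
#' @param dir output directory, created if absent.
#' @return Invisibly, `dir`.
#' @export
save_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- session$trials
  utils::write.csv(data.frame(
    trial_id = tr$trial_id, cue_type = tr$cue_type,
    cue_onset_s = tr$cue_onset, cue_offset_s = tr$cue_offset,
    reward_time_s = tr$reward_time
  ), file.path(dir, "trials.csv"), row.names = FALSE, na = "")
  sp <- data.frame(
    unit_id = rep(names(session$units), lengths(session$units)),
    spike_time_s = unlist(session$units, use.names = FALSE)
  )
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(port_entry_time_s = session$port_entries),
                   file.path(dir, "entries.csv"), row.names = FALSE)
  if (!is.null(session$tracking))
    utils::write.csv(session$tracking, file.path(dir, "tracking.csv"),
                     row.names = FALSE)
  meta <- list(task_kind = session$task_kind,
               session_duration = session$session_duration)
  if (!is.null(session$port_xy)) meta$port_xy <- as.numeric(session$port_xy)
  yaml::write_yaml(meta, file.path(dir, "session.yaml"))
  invisible(dir)
}

#' Load a session from a directory written by [save_session()]
#'
#' @param dir directory containing the CSV files and `session.yaml`.
#' @return A validated `vp_session`.
#' @export
load_session_dir <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "session.yaml"))
  tf <- file.path(dir, "tracking.csv")
  load_session(file.path(dir, "trials.csv"), file.path(dir, "spikes.csv"),
               file.path(dir, "entries.csv"),
               tracking_file = if (file.exists(tf)) tf else NULL,
               task_kind = meta$task_kind,
               port_xy = meta$port_xy,
               session_duration = meta$session_duration)
}
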