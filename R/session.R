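# Session data model: trials, spike trains, port entries, optional tracking.
#
# A session is the unit of recording: one rat, one day, one task contingency
# (Pavlovian or instrumental), a trial table, session-wide port-entry times,
# one spike train per isolated unit, and (optionally) an overhead tracking
# trace at 30 frames/s.

#' Construct a recording session
#'
#' Bundles the trial table, per-unit spike trains, session-wide port entries
#' and an optional tracking trace into a validated `vp_session` object.
#'
#' @param trials data.frame with columns `trial_id` (integer), `cue_type`
#'   ("reward" or "control"), `cue_onset`, `cue_offset` (seconds from session
#'   start) and `reward_time` (seconds, `NA` when no reward was delivered).
#' @param units named list of numeric vectors; each element is one unit's
#'   spike times in seconds, strictly increasing.
#' @param port_entries numeric vector of port-entry times (seconds), sorted.
#' @param task_kind "pavlovian" or "instrumental".
#' @param tracking optional data.frame with columns `frame`, `t_s`, `x_cm`,
#'   `y_cm`, `missing` (0/1); frame times at 30 frames/s.
#' @param port_xy numeric length-2, reward-port coordinates (cm); required
#'   when `tracking` is given.
#' @param session_duration session length in seconds; defaults to just past
#'   the last event.
#' @return An object of class `vp_session`.
#' @export
vp_session <- function(trials, units, port_entries, task_kind,
                       tracking = NULL, port_xy = NULL,
                       session_duration = NULL) {
  task_kind <- match.arg(task_kind, c("pavlovian", "instrumental"))
  port_entries <- sort(as.numeric(port_entries))
  if (is.null(session_duration)) {
    last <- max(c(trials$cue_offset, port_entries, unlist(units), 0))
    session_duration <- last + 1
  }
  x <- structure(list(
    task_kind = task_kind,
    trials = trials,
    units = units,
    port_entries = port_entries,
    tracking = tracking,
    port_xy = port_xy,
    session_duration = session_duration
  ), class = "vp_session")
  validate_session(x)
  x
}

#' Validate a session against its structural invariants
#'
#' Checks trial ordering and non-overlap, cue durations (<= 10 s), reward
#' timing (within cue, or up to 2 s past offset), spike-train monotonicity
#' and bounds, and tracking frame-rate regularity. Stops with a validation
#' error naming the violated invariant.
#'
#' @param session a `vp_session`.
#' @return Invisibly `TRUE` when valid.
#' @export
validate_session <- function(session) {
  tr <- session$trials
  need <- c("trial_id", "cue_type", "cue_onset", "cue_offset", "reward_time")
  if (!all(need %in% names(tr)))
    stop_validation("trial table missing columns: ",
                    paste(setdiff(need, names(tr)), collapse = ", "))
  if (!all(tr$cue_type %in% c("reward", "control")))
    stop_validation("cue_type must be 'reward' or 'control'")
  if (any(tr$cue_onset >= tr$cue_offset))
    stop_validation("invariant violated: cue_onset < cue_offset")
  if (any(tr$cue_offset - tr$cue_onset > 10 + 1e-9))
    stop_validation("invariant violated: cue duration <= 10 s")
  if (is.unsorted(tr$cue_onset, strictly = TRUE))
    stop_validation("invariant violated: trials ordered by onset")
  if (nrow(tr) > 1 && any(tr$cue_onset[-1] < tr$cue_offset[-nrow(tr)]))
    stop_validation("invariant violated: trials non-overlapping")
  rw <- !is.na(tr$reward_time)
  if (any(rw & (tr$reward_time < tr$cue_onset - 1e-9 |
                tr$reward_time > tr$cue_offset + 2 + 1e-9)))
    stop_validation("invariant violated: reward_time in [cue_onset, cue_offset + 2 s]")
  for (uid in names(session$units)) {
    st <- session$units[[uid]]
    if (length(st) && (is.unsorted(st, strictly = TRUE)))
      stop_validation("invariant violated: spike times strictly increasing (unit ",
                      uid, ")")
    if (length(st) && (st[1] < 0 || st[length(st)] > session$session_duration))
      stop_validation("invariant violated: spike times within [0, session_duration] (unit ",
                      uid, ")")
  }
  if (!is.null(session$tracking)) {
    tk <- session$tracking
    if (!all(c("frame", "t_s", "x_cm", "y_cm", "missing") %in% names(tk)))
      stop_validation("tracking table missing columns")
    dt <- diff(tk$t_s)
    if (length(dt) && (any(dt <= 0) || max(abs(dt - 1 / 30)) > 1e-6))
      stop_validation("invariant violated: tracking frames at constant 1/30 s step")
    ok <- tk$missing == 0
    if (any(!is.finite(tk$x_cm[ok])) || any(!is.finite(tk$y_cm[ok])))
      stop_validation("invariant violated: x,y finite where not missing")
    if (is.null(session$port_xy) || length(session$port_xy) != 2)
      stop_validation("port_xy required with tracking")
  }
  invisible(TRUE)
}

#' @export
print.vp_session <- function(x, ...) {
  cat(sprintf("<vp_session> %s task: %d trials (%d reward), %d units, %d port entries%s\n",
              x$task_kind, nrow(x$trials), sum(x$trials$cue_type == "reward"),
              length(x$units), length(x$port_entries),
              if (is.null(x$tracking)) "" else ", tracking"))
  invisible(x)
}

#' Latency from cue onset to the first in-cue port entry
#'
#' The latency is the time from cue onset to the first port entry in the
#' half-open window [cue_onset, cue_offset); entries before onset are
#' ignored; `NA` when no entry occurs during the cue.
#'
#' @param cue_onset,cue_offset trial cue window (seconds).
#' @param port_entries sorted numeric vector of session-wide entry times.
#' @return Latency in seconds, or `NA_real_`.
#' @export
trial_latency <- function(cue_onset, cue_offset, port_entries) {
  hit <- port_entries[port_entries >= cue_onset & port_entries < cue_offset]
  if (length(hit) == 0) return(NA_real_)
  hit[1] - cue_onset
}

#' Per-trial response latencies for a session
#'
#' Uses the half-open window `[cue_onset, cue_offset)`, except on trials
#' whose cue was terminated by the rewarded entry itself (instrumental
#' contingency, `reward_time == cue_offset`): there the window closes at
#' the offset so the terminating entry counts.
#'
#' @param session a `vp_session`.
#' @return Numeric vector, one latency (or `NA`) per trial, in trial order.
#' @export
trial_latencies <- function(session) {
  tr <- session$trials
  vapply(seq_len(nrow(tr)), function(i) {
    hi <- tr$cue_offset[i]
    if (!is.na(tr$reward_time[i]) && tr$reward_time[i] >= hi - 1e-9)
      hi <- hi + 1e-9
    trial_latency(tr$cue_onset[i], hi, session$port_entries)
  }, numeric(1))
}

#' Probability of an in-cue port entry for one cue type
#'
#' @param session a `vp_session`.
#' @param cue_type "reward" or "control".
#' @return Fraction of trials of that cue type with a defined latency.
#' @export
response_probability <- function(session, cue_type = c("reward", "control")) {
  cue_type <- match.arg(cue_type)
  sel <- session$trials$cue_type == cue_type
  if (!any(sel)) stop("no trials of cue type '", cue_type, "'")
  lat <- trial_latencies(session)[sel]
  mean(!is.na(lat))
}

#' Training-criterion rule
#'
#' Final response criterion: port entries on at least 70% of reward-cue
#' (DS / CS+) presentations and less than 30% (strict) of control-cue
#' (NS / CS-) presentations.
#'
#' @param p_reward,p_control response probabilities per cue type.
#' @return Logical flag.
#' @export
criterion_met <- function(p_reward, p_control) {
  isTRUE(p_reward >= 0.70 && p_control < 0.30)
}

#' Port-entry rate during the inter-trial interval
#'
#' Entries outside all cue windows, divided by the total non-cue time,
#' scaled to entries per minute.
#'
#' @param session a `vp_session`.
#' @return Entries per minute.
#' @export
iti_port_entry_rate <- function(session) {
  tr <- session$trials
  in_cue <- rep(FALSE, length(session$port_entries))
  for (i in seq_len(nrow(tr)))
    in_cue <- in_cue | (session$port_entries >= tr$cue_onset[i] &
                        session$port_entries < tr$cue_offset[i])
  cue_time <- sum(tr$cue_offset - tr$cue_onset)
  iti_time <- session$session_duration - cue_time
  if (iti_time <= 0) stop("session_duration must exceed total cue time")
  sum(!in_cue) / iti_time * 60
}

#' Behavioral summary for a session
#'
#' @param session a `vp_session`.
#' @return List with per-cue-type response probabilities, latency mean/SD
#'   over responded trials, ITI entry rate (entries/min) and the
#'   training-criterion flag.
#' @export
behavior_summary <- function(session) {
  lat <- trial_latencies(session)
  tr <- session$trials
  out <- list()
  for (ct in c("reward", "control")) {
    sel <- tr$cue_type == ct
    l <- lat[sel]
    out[[paste0("p_respond_", ct)]] <- if (any(sel)) mean(!is.na(l)) else NA_real_
    out[[paste0("latency_mean_", ct)]] <- mean(l, na.rm = TRUE)
    out[[paste0("latency_sd_", ct)]] <- stats::sd(l[!is.na(l)])
  }
  out$iti_entry_rate <- iti_port_entry_rate(session)
  out$criterion_met <- criterion_met(out$p_respond_reward, out$p_respond_control)
  out
}
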