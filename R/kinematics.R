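# Tracking-trace processing: gap interpolation, frame velocity, port
# distance, movement-onset detection.

#' Fill missing tracking frames by linear interpolation
#'
#' Interior gaps are linearly interpolated per coordinate; leading and
#' trailing gaps are held at the nearest observed value. The original
#' `missing` flags are preserved for audit, and frames inside gaps longer
#' than `max_gap_s` are additionally flagged in an `excluded` column (trials
#' overlapping such gaps should be dropped from kinematics).
#'
#' @param trace tracking data.frame (`frame`, `t_s`, `x_cm`, `y_cm`,
#'   `missing`).
#' @param max_gap_s longest interpolatable gap (s), default 1.
#' @return The trace with `x_cm`/`y_cm` filled and an `excluded` column.
#' @export
interpolate_positions <- function(trace, max_gap_s = 1) {
  out <- trace
  obs <- which(trace$missing == 0)
  if (length(obs) < 2) stop("too few observed frames to interpolate")
  for (col in c("x_cm", "y_cm")) {
    out[[col]] <- stats::approx(trace$t_s[obs], trace[[col]][obs],
                                xout = trace$t_s, rule = 2)$y
  }
  excluded <- rep(FALSE, nrow(trace))
  r <- rle(trace$missing == 1)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  gap_frames <- as.integer(round(max_gap_s * 30))
  for (g in which(r$values & r$lengths > gap_frames))
    excluded[starts[g]:ends[g]] <- TRUE
  out$excluded <- excluded
  out
}

#' Frame-by-frame velocity
#'
#' 30 x Euclidean displacement between consecutive frames; the first frame
#' has velocity 0. No smoothing is applied.
#'
#' @param trace interpolated tracking data.frame.
#' @return Numeric vector of velocities (cm/s), one per frame.
#' @export
frame_velocity <- function(trace) {
  dx <- diff(trace$x_cm); dy <- diff(trace$y_cm)
  c(0, 30 * sqrt(dx^2 + dy^2))
}

#' Distance from the reward port at a time point
#'
#' Euclidean distance from the position at the frame nearest `t` to the
#' port; `NA` when that frame is excluded.
#'
#' @param trace interpolated tracking data.frame.
#' @param t time (s).
#' @param port_xy numeric length-2 port coordinates (cm).
#' @return Distance (cm) or `NA_real_`.
#' @export
distance_to_port <- function(trace, t, port_xy) {
  i <- which.min(abs(trace$t_s - t))
  if (!is.null(trace$excluded) && trace$excluded[i]) return(NA_real_)
  sqrt((trace$x_cm[i] - port_xy[1])^2 + (trace$y_cm[i] - port_xy[2])^2)
}

#' Movement-onset latency from the velocity trace
#'
#' The onset is the time of the first frame beginning a run of at least
#' `run_len` consecutive frames whose velocity exceeds the upper limit of
#' the 95% band of the baseline velocity (the 5 s pre-cue frames): mean +
#' 1.96 * SD, a one-sided upward exceedance since approach can only raise
#' velocity. Zero baseline variance falls back to an epsilon SD floor of
#' 0.1 cm/s (flagged via attribute `sd_floored`).
#'
#' @param velocity per-frame velocities (cm/s).
#' @param frame_times per-frame times (s).
#' @param cue_onset cue-onset time (s).
#' @param horizon search horizon after cue onset (s), default 10.
#' @param baseline_s pre-cue baseline length (s), default 5.
#' @param run_len required consecutive supra-threshold frames, default 5.
#' @param level band coverage, default 0.95.
#' @return Latency (s) from cue onset, or `NA_real_`; attribute
#'   `sd_floored` marks the degenerate-baseline fallback.
#' @export
movement_onset <- function(velocity, frame_times, cue_onset, horizon = 10,
                           baseline_s = 5, run_len = 5, level = 0.95) {
  base <- frame_times >= cue_onset - baseline_s & frame_times < cue_onset
  if (sum(base) < baseline_s * 30 * 0.9)
    stop("need >= ", baseline_s, " s of pre-cue frames")
  m <- mean(velocity[base]); s <- stats::sd(velocity[base])
  floored <- FALSE
  if (!is.finite(s) || s == 0) { s <- 0.1; floored <- TRUE }
  thr <- m + stats::qnorm(1 - (1 - level) / 2) * s
  idx <- which(frame_times >= cue_onset & frame_times < cue_onset + horizon)
  above <- velocity[idx] > thr
  run <- 0L
  for (k in seq_along(above)) {
    run <- if (above[k]) run + 1L else 0L
    if (run == run_len) {
      onset <- frame_times[idx[k - run_len + 1L]] - cue_onset
      return(structure(onset, sd_floored = floored))
    }
  }
  structure(NA_real_, sd_floored = floored)
}

#' Per-trial kinematic variables
#'
#' Distance from the port at cue onset, mean velocity over [0, 0.5) and
#' [0.5, 1.0) s post-cue, and movement-onset latency for every trial.
#' Trials overlapping excluded tracking gaps get `NA` throughout.
#'
#' @param trace tracking data.frame (interpolated automatically if it lacks
#'   an `excluded` column).
#' @param trials trial table.
#' @param port_xy port coordinates (cm).
#' @param horizon movement-onset search horizon (s).
#' @return data.frame with columns `trial_id`, `distance`, `vel_early`,
#'   `vel_late`, `move_onset`.
#' @export
trial_kinematics <- function(trace, trials, port_xy, horizon = 10) {
  if (is.null(trace$excluded)) trace <- interpolate_positions(trace)
  v <- frame_velocity(trace)
  n <- nrow(trials)
  out <- data.frame(trial_id = trials$trial_id, distance = NA_real_,
                    vel_early = NA_real_, vel_late = NA_real_,
                    move_onset = NA_real_)
  for (i in seq_len(n)) {
    t0 <- trials$cue_onset[i]
    span <- trace$t_s >= t0 - 5 & trace$t_s < t0 + min(horizon, 10)
    if (any(trace$excluded[span])) next
    out$distance[i] <- distance_to_port(trace, t0, port_xy)
    e <- trace$t_s >= t0 & trace$t_s < t0 + 0.5
    l <- trace$t_s >= t0 + 0.5 & trace$t_s < t0 + 1
    out$vel_early[i] <- mean(v[e])
    out$vel_late[i] <- mean(v[l])
    mo <- try(movement_onset(v, trace$t_s, t0, horizon = horizon),
              silent = TRUE)
    if (!inherits(mo, "try-error")) out$move_onset[i] <- as.numeric(mo)
  }
  out
}
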