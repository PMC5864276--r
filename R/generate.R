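# Synthetic-session generator.
#
# Emulates the two task structures the analyses assume:
#  * instrumental "DS task": reward cue up to 10 s; a port entry during the
#    cue delivers sucrose and terminates the cue; control cue has no
#    programmed consequence; mean ITI 50 s.
#  * Pavlovian conditioning: 10 s CS+ with reward delivered 8 s after onset
#    regardless of behavior; 10 s CS- never rewarded.
# Units fire as inhomogeneous Poisson processes: baseline rate plus a boxcar
# cue response whose per-trial gain can be coupled to the behavioral
# response latency and/or the animal's distance from the port at cue onset.
# Tracking traces wander at a baseline speed pre-cue and approach the port
# in a straight line on responded trials.

#' Behavioral generator parameters
#'
#' @param task_kind "pavlovian" or "instrumental".
#' @param n_reward_trials,n_control_trials trial counts per cue type.
#' @param iti_mean mean inter-trial interval (s); ITIs are drawn i.i.d.
#'   uniform on `iti_range`.
#' @param iti_range numeric length-2; defaults to `iti_mean + c(-25, 25)`.
#' @param cue_duration cue length (s), at most 10.
#' @param p_respond_reward,p_respond_control per-trial probability of an
#'   in-cue port entry.
#' @param latency_meanlog,latency_sdlog lognormal law for entry latency (s),
#'   truncated to (0, cue_duration).
#' @param iti_entry_rate rate of nonspecific port entries during the ITI
#'   (entries per second).
#' @return Parameter list of class `behavior_gen_params`.
#' @export
behavior_gen_params <- function(task_kind = "instrumental",
                                n_reward_trials = 30, n_control_trials = 30,
                                iti_mean = 50, iti_range = NULL,
                                cue_duration = 10,
                                p_respond_reward = 0.9,
                                p_respond_control = 0.2,
                                latency_meanlog = log(1.5),
                                latency_sdlog = 0.6,
                                iti_entry_rate = 1.5 / 60) {
  task_kind <- match.arg(task_kind, c("pavlovian", "instrumental"))
  if (is.null(iti_range)) iti_range <- iti_mean + c(-25, 25)
  stopifnot(p_respond_reward >= 0, p_respond_reward <= 1,
            p_respond_control >= 0, p_respond_control <= 1,
            cue_duration > 0, cue_duration <= 10,
            abs(mean(iti_range) - iti_mean) < 1e-9)
  if (stats::plnorm(cue_duration, latency_meanlog, latency_sdlog) < 0.5)
    stop("infeasible latency law: more than half its mass beyond cue_duration")
  structure(as.list(environment()), class = "behavior_gen_params")
}

#' Unit generator parameters
#'
#' @param unit_id label for the generated unit.
#' @param baseline_rate baseline firing rate lambda0 (Hz), >= 0.
#' @param response_kind "excited", "inhibited" or "none".
#' @param response_amplitude boxcar amplitude (Hz); its sign is forced to
#'   match `response_kind` and the total instantaneous rate is floored at 0.
#' @param response_onset boxcar start relative to cue onset (s).
#' @param response_duration boxcar length (s).
#' @param latency_coupling beta: per-trial gain `exp(-beta * z(latency))`
#'   multiplying the amplitude, z the within-session rank-normalized entry
#'   latency over responded reward trials. beta > 0 makes short-latency
#'   trials stronger (negative firing-latency correlation).
#' @param distance_coupling gamma: same form on the rank-normalized distance
#'   from the port at cue onset (requires tracking).
#' @param control_cue_amplitude boxcar amplitude on control-cue trials (Hz).
#' @return Parameter list of class `unit_gen_params`.
#' @export
unit_gen_params <- function(unit_id = "u1", baseline_rate = 10,
                            response_kind = c("excited", "inhibited", "none"),
                            response_amplitude = 15,
                            response_onset = 0.05, response_duration = 0.5,
                            latency_coupling = 0, distance_coupling = 0,
                            control_cue_amplitude = 0) {
  response_kind <- match.arg(response_kind)
  stopifnot(baseline_rate >= 0, response_duration > 0)
  response_amplitude <- switch(response_kind,
    excited = abs(response_amplitude),
    inhibited = -abs(response_amplitude),
    none = 0)
  structure(as.list(environment()), class = "unit_gen_params")
}

#' Tracking generator parameters
#'
#' @param arena_cm arena side length (cm); square arena with corner at the
#'   origin.
#' @param port_xy reward-port coordinates (cm).
#' @param baseline_speed mean wandering speed (cm/s) outside approaches.
#' @param approach_speed straight-line approach speed toward the port (cm/s).
#' @param start_distance_range uniform law (cm) for the starting distance
#'   from the port.
#' @param missing_fraction fraction of frames flagged missing (< 0.2).
#' @param movement_onset_delay optional fixed movement-onset time (s after
#'   cue onset) on responded trials; when `NULL` the onset is set so that a
#'   straight approach at `approach_speed` reaches the port at the entry
#'   time.
#' @return Parameter list of class `tracking_gen_params`.
#' @export
tracking_gen_params <- function(arena_cm = 40, port_xy = c(38, 20),
                                baseline_speed = 4, approach_speed = 30,
                                start_distance_range = c(10, 30),
                                missing_fraction = 0.05,
                                movement_onset_delay = NULL) {
  stopifnot(missing_fraction >= 0, missing_fraction < 0.2,
            approach_speed > 0, baseline_speed >= 0)
  structure(as.list(environment()), class = "tracking_gen_params")
}

rtrunc_lnorm <- function(n, meanlog, sdlog, upper) {
  pmax_u <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, 0, pmax_u), meanlog, sdlog)
}

#' Generate trials and port entries for one session
#'
#' Reward and control trials are interleaved in randomized order with i.i.d.
#' uniform ITIs. Responded trials receive an in-cue port entry at a
#' truncated-lognormal latency. Under the instrumental contingency, a
#' responded reward trial terminates the cue at the entry time and the
#' reward is delivered at entry; under the Pavlovian contingency the reward
#' arrives 8 s after CS+ onset on every reward trial regardless of behavior.
#' Nonspecific port entries are added during ITIs as a Poisson process.
#'
#' @param params a [behavior_gen_params()] list.
#' @param seed integer seed; same seed, same output.
#' @return List with `trials` (data.frame), `port_entries`, `latencies`
#'   (per trial, `NA` when not responded) and `session_duration`.
#' @export
generate_behavior <- function(params, seed) {
  stopifnot(inherits(params, "behavior_gen_params"))
  with_seed(seed, {
    p <- params
    n <- p$n_reward_trials + p$n_control_trials
    cue_type <- sample(rep(c("reward", "control"),
                           c(p$n_reward_trials, p$n_control_trials)))
    responded <- stats::runif(n) < ifelse(cue_type == "reward",
                                          p$p_respond_reward,
                                          p$p_respond_control)
    latency <- rep(NA_real_, n)
    latency[responded] <- rtrunc_lnorm(sum(responded), p$latency_meanlog,
                                       p$latency_sdlog, p$cue_duration)
    itis <- stats::runif(n, p$iti_range[1], p$iti_range[2])
    onset <- offset <- reward <- numeric(n)
    t <- 0
    for (i in seq_len(n)) {
      onset[i] <- t + itis[i]
      offset[i] <- onset[i] + p$cue_duration
      reward[i] <- NA_real_
      if (cue_type[i] == "reward") {
        if (p$task_kind == "pavlovian") {
          reward[i] <- onset[i] + 8
        } else if (responded[i]) {
          offset[i] <- onset[i] + latency[i]
          reward[i] <- offset[i]
        }
      }
      t <- offset[i]
    }
    session_duration <- t + stats::runif(1, p$iti_range[1], p$iti_range[2])
    entries <- onset[responded] + latency[responded]
    # nonspecific entries in the gaps between cues
    gap_lo <- c(0, offset)
    gap_hi <- c(onset, session_duration)
    for (g in seq_along(gap_lo)) {
      len <- gap_hi[g] - gap_lo[g]
      if (len <= 0) next
      k <- stats::rpois(1, p$iti_entry_rate * len)
      if (k > 0) entries <- c(entries, stats::runif(k, gap_lo[g], gap_hi[g]))
    }
    trials <- data.frame(trial_id = seq_len(n), cue_type = cue_type,
                         cue_onset = onset, cue_offset = offset,
                         reward_time = reward, stringsAsFactors = FALSE)
    list(trials = trials, port_entries = sort(entries),
         latencies = latency, session_duration = session_duration)
  })
}

#' Per-trial response gains for a generated unit
#'
#' `exp(-beta * z(latency)) * exp(-gamma * z(distance))`, each factor 1 where
#' its covariate is undefined; z is the rank-normal score within the session.
#' @noRd
trial_gains <- function(params, trials, latencies, distances = NULL) {
  n <- nrow(trials)
  g <- rep(1, n)
  rw <- trials$cue_type == "reward"
  if (params$latency_coupling != 0) {
    idx <- which(rw & !is.na(latencies))
    if (length(idx) >= 2)
      g[idx] <- g[idx] * exp(-params$latency_coupling *
                               rank_normalize(latencies[idx]))
  }
  if (params$distance_coupling != 0 && !is.null(distances)) {
    idx <- which(rw & !is.na(distances))
    if (length(idx) >= 2)
      g[idx] <- g[idx] * exp(-params$distance_coupling *
                               rank_normalize(distances[idx]))
  }
  g
}

#' Generate one unit's spike train
#'
#' Inhomogeneous Poisson process with piecewise-constant rate: baseline
#' `baseline_rate` everywhere, plus a per-trial boxcar of amplitude
#' `gain * response_amplitude` on reward trials (and `control_cue_amplitude`
#' on control trials) over `[onset + response_onset, onset + response_onset +
#' response_duration)`. The total rate is floored at 0 Hz. Excitations are
#' generated by superposition, inhibitions by exact thinning of the baseline
#' process.
#'
#' @param params a [unit_gen_params()] list.
#' @param trials trial table (as from [generate_behavior()]).
#' @param session_duration seconds.
#' @param seed integer seed.
#' @param latencies optional per-trial entry latencies (for
#'   `latency_coupling`).
#' @param distances optional per-trial port distance at cue onset (for
#'   `distance_coupling`).
#' @return Sorted numeric vector of spike times (seconds).
#' @export
generate_unit_spikes <- function(params, trials, session_duration, seed,
                                 latencies = NULL, distances = NULL) {
  stopifnot(inherits(params, "unit_gen_params"))
  if (is.null(latencies)) latencies <- rep(NA_real_, nrow(trials))
  gains <- trial_gains(params, trials, latencies, distances)
  with_seed(seed, {
    lam0 <- params$baseline_rate
    nb <- stats::rpois(1, lam0 * session_duration)
    spikes <- stats::runif(nb, 0, session_duration)
    for (i in seq_len(nrow(trials))) {
      amp <- if (trials$cue_type[i] == "reward")
        gains[i] * params$response_amplitude else params$control_cue_amplitude
      if (amp == 0) next
      w0 <- trials$cue_onset[i] + params$response_onset
      w1 <- w0 + params$response_duration
      w1 <- min(w1, session_duration)
      if (w1 <= w0) next
      if (amp > 0) {
        k <- stats::rpois(1, amp * (w1 - w0))
        if (k > 0) spikes <- c(spikes, stats::runif(k, w0, w1))
      } else {
        keep_p <- if (lam0 > 0) max(0, lam0 + amp) / lam0 else 0
        inwin <- spikes >= w0 & spikes < w1
        drop <- inwin & (stats::runif(length(spikes)) > keep_p)
        spikes <- spikes[!drop]
      }
    }
    unique(sort(spikes))
  })
}

#' Generate an overhead tracking trace
#'
#' 30 frames/s. Between approaches, the animal wanders as a smooth random
#' walk at the baseline speed, reflected at the arena walls. On each
#' responded trial the trace turns toward the port at the movement onset and
#' arrives at the entry time, then holds near the port for 2 s. A random
#' subset of frames is flagged missing.
#'
#' @param params a [tracking_gen_params()] list.
#' @param trials trial table.
#' @param session_duration seconds.
#' @param seed integer seed.
#' @param latencies per-trial entry latencies (`NA` = not responded).
#' @return data.frame with `frame`, `t_s`, `x_cm`, `y_cm`, `missing`.
#' @export
generate_tracking <- function(params, trials, session_duration, seed,
                              latencies) {
  stopifnot(inherits(params, "tracking_gen_params"))
  with_seed(seed, {
    p <- params
    dt <- 1 / 30
    t_s <- seq(0, session_duration, by = dt)
    nf <- length(t_s)
    x <- y <- numeric(nf)
    # approach segments: (start, entry) per responded trial
    resp <- which(!is.na(latencies))
    entry_t <- trials$cue_onset[resp] + latencies[resp]
    seg <- data.frame(onset = trials$cue_onset[resp], entry = entry_t)
    seg <- seg[order(seg$onset), , drop = FALSE]
    # initial position: drawn distance from port, random direction, clipped
    d0 <- stats::runif(1, p$start_distance_range[1], p$start_distance_range[2])
    th <- stats::runif(1, 0, 2 * pi)
    pos <- pmin(pmax(p$port_xy + d0 * c(cos(th), sin(th)), 0.5), p$arena_cm - 0.5)
    heading <- stats::runif(1, 0, 2 * pi)
    hold_until <- -Inf
    approach_i <- 0L         # index into seg of the active approach
    approach_start <- Inf
    next_seg <- 1L
    for (f in seq_len(nf)) {
      tt <- t_s[f]
      x[f] <- pos[1]; y[f] <- pos[2]
      # arm the next approach once its cue has started
      if (next_seg <= nrow(seg) && tt >= seg$onset[next_seg] &&
          approach_i == 0L) {
        d <- sqrt(sum((pos - p$port_xy)^2))
        st <- if (is.null(p$movement_onset_delay))
          seg$entry[next_seg] - d / p$approach_speed
        else seg$onset[next_seg] + p$movement_onset_delay
        approach_start <- max(seg$onset[next_seg], st)
        approach_i <- next_seg
        next_seg <- next_seg + 1L
      }
      if (approach_i > 0L && tt >= seg$entry[approach_i]) {
        hold_until <- seg$entry[approach_i] + 2
        approach_start <- Inf
        approach_i <- 0L
      }
      if (approach_i > 0L && tt >= approach_start) {
        # straight-line approach timed to reach the port at the entry time
        remain <- seg$entry[approach_i] - tt
        d <- sqrt(sum((pos - p$port_xy)^2))
        if (remain <= dt || d < 1e-6) {
          pos <- p$port_xy
        } else {
          pos <- pos + (p$port_xy - pos) * min(1, dt / remain)
        }
      } else if (tt < hold_until) {
        pos <- p$port_xy + stats::rnorm(2, 0, 0.1)
      } else {
        heading <- heading + stats::rnorm(1, 0, 0.5)
        sp <- abs(stats::rnorm(1, p$baseline_speed, p$baseline_speed / 3))
        pos <- pos + sp * dt * c(cos(heading), sin(heading))
        pos <- pmin(pmax(pos, 0.5), p$arena_cm - 0.5)
      }
    }
    missing <- rep(0L, nf)
    if (p$missing_fraction > 0) {
      k <- floor(p$missing_fraction * nf)
      if (k > 0) {
        idx <- sample(nf, k)
        missing[idx] <- 1L
        x[idx] <- NA_real_; y[idx] <- NA_real_
      }
    }
    data.frame(frame = seq_len(nf), t_s = t_s, x_cm = x, y_cm = y,
               missing = missing)
  })
}

#' Generate a complete synthetic session
#'
#' Composes the behavior, tracking and spike generators under sub-seeds
#' derived from one master seed; the returned session passes full
#' validation.
#'
#' @param config list with elements `behavior` ([behavior_gen_params()]),
#'   `units` (list of [unit_gen_params()]), and optionally `tracking`
#'   ([tracking_gen_params()]).
#' @param seed master integer seed.
#' @return A `vp_session`.
#' @export
generate_session <- function(config, seed) {
  beh <- generate_behavior(config$behavior, derive_seed(seed, "behavior"))
  tracking <- NULL
  port_xy <- NULL
  distances <- NULL
  if (!is.null(config$tracking)) {
    tracking <- generate_tracking(config$tracking, beh$trials,
                                  beh$session_duration,
                                  derive_seed(seed, "tracking"),
                                  beh$latencies)
    port_xy <- config$tracking$port_xy
    filled <- interpolate_positions(tracking)
    distances <- vapply(beh$trials$cue_onset, function(t0)
      distance_to_port(filled, t0, port_xy), numeric(1))
  }
  units <- list()
  for (i in seq_along(config$units)) {
    up <- config$units[[i]]
    uid <- up$unit_id %||% paste0("u", i)
    units[[uid]] <- generate_unit_spikes(up, beh$trials, beh$session_duration,
                                         derive_seed(seed, paste0("unit_", i)),
                                         latencies = beh$latencies,
                                         distances = distances)
  }
  vp_session(beh$trials, units, beh$port_entries, config$behavior$task_kind,
             tracking = tracking, port_xy = port_xy,
             session_duration = beh$session_duration)
}

#' Default simulation configuration
#'
#' A session emulating the study conditions: 30 reward + 30 control trials,
#' mean ITI 50 s, 10 s cues, and a unit population spanning cue-excited,
#' cue-inhibited and unmodulated cells.
#'
#' @param task_kind "pavlovian" or "instrumental".
#' @param n_excited,n_inhibited,n_none unit counts per response class.
#' @param latency_coupling beta applied to the excited units.
#' @param with_tracking include a tracking trace?
#' @return Config list for [generate_session()].
#' @export
default_sim_config <- function(task_kind = "instrumental",
                               n_excited = 6, n_inhibited = 3, n_none = 3,
                               latency_coupling = 0,
                               with_tracking = FALSE) {
  units <- c(
    lapply(seq_len(n_excited), function(i)
      unit_gen_params(paste0("exc", i), response_kind = "excited",
                      latency_coupling = latency_coupling)),
    lapply(seq_len(n_inhibited), function(i)
      unit_gen_params(paste0("inh", i), baseline_rate = 15,
                      response_kind = "inhibited", response_amplitude = 12)),
    lapply(seq_len(n_none), function(i)
      unit_gen_params(paste0("non", i), response_kind = "none"))
  )
  list(behavior = behavior_gen_params(task_kind = task_kind),
       units = units,
       tracking = if (with_tracking) tracking_gen_params() else NULL)
}
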