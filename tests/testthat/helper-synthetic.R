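# Shared fixture builders: small deterministic sessions and spike trains.

# behavior with exactly n_resp responded reward trials (p_respond = 1)
make_behavior <- function(seed, n_reward = 25, n_control = 5,
                          p_reward = 1, p_control = 0.2) {
  generate_behavior(
    behavior_gen_params(n_reward_trials = n_reward,
                        n_control_trials = n_control,
                        p_respond_reward = p_reward,
                        p_respond_control = p_control),
    seed)
}

# hand-built minimal session: two reward + two control trials
make_tiny_session <- function() {
  trials <- data.frame(
    trial_id = 1:4,
    cue_type = c("reward", "control", "reward", "control"),
    cue_onset = c(100, 160, 220, 280),
    cue_offset = c(110, 170, 230, 290),
    reward_time = c(101.2, NA, NA, NA))
  vp_session(trials,
             units = list(u1 = c(0.5, 50, 101, 150.2, 225)),
             port_entries = c(20, 101.2, 140, 250),
             task_kind = "instrumental",
             session_duration = 340)
}

# rates/latencies pair for a null (uncoupled) unit, Poisson counts
make_null_unit <- function(n = 25, lambda = 3) {
  list(rates = stats::rpois(n, lambda) / 0.3,
       latencies = stats::rlnorm(n, log(1.5), 0.6))
}

# fabricate a vp_psth with a given per-bin trial-mean rate (1 "trial")
fake_psth <- function(rates, bin_size = 0.01, start = -10) {
  nb <- length(rates)
  structure(list(label = "fake",
                 counts = matrix(rates * bin_size, nrow = 1),
                 bin_edges = start + bin_size * (0:nb),
                 bin_size = bin_size,
                 window = c(start, start + nb * bin_size),
                 trial_mean_rate = rates),
            class = "vp_psth")
}
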