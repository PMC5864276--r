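# Response detection: bands, crossing classification, telescopic onset,
# offset rule, nonparametric direction tests.

test_that("baseline band has the closed-form limits", {
  set.seed(3)
  rates <- rnorm(1000, 10, 2)
  psth <- fake_psth(rates, bin_size = 0.01, start = -10)
  b99 <- baseline_band(psth, 0.99)
  expect_equal(b99$lo, mean(rates) - qnorm(0.995) * sd(rates), tolerance = 1e-12)
  expect_equal(b99$hi, mean(rates) + qnorm(0.995) * sd(rates), tolerance = 1e-12)
  expect_equal(b99$hi - b99$mean, 2.576 * b99$sd, tolerance = 1e-3)
  b95 <- baseline_band(psth, 0.95)
  expect_equal(b95$hi - b95$mean, 1.96 * b95$sd, tolerance = 1e-3)
  # SEM variant shrinks with baseline length
  bsem <- baseline_band(psth, 0.99, band_kind = "sem")
  expect_lt(bsem$hi - bsem$mean, (b99$hi - b99$mean) / 10)
  # SD = 0 flags instead of classifying
  expect_true(baseline_band(fake_psth(rep(5, 1000)), 0.99)$unclassifiable)
})

test_that("detect_response classifies by first band crossing", {
  base <- rep(c(9, 11), 500)                      # mean 10, sd ~1
  mk <- function(post) fake_psth(c(base, post), 0.01, -10)
  band <- baseline_band(mk(rep(10, 100)), 0.99)
  expect_equal(detect_response(mk(rep(10, 100)), band, c(0, 1))$direction,
               "none")
  up <- detect_response(mk(c(rep(10, 20), rep(30, 30), rep(10, 50))),
                        band, c(0, 1))
  expect_equal(up$direction, "excited")
  expect_equal(up$first_crossing_bin, 0.2)
  down <- detect_response(mk(c(rep(10, 20), rep(2, 30), rep(10, 50))),
                          band, c(0, 1))
  expect_equal(down$direction, "inhibited")
  # both directions crossed: first in time wins
  both <- detect_response(mk(c(rep(2, 10), rep(30, 20), rep(10, 70))),
                          band, c(0, 1))
  expect_equal(both$direction, "inhibited")
})

test_that("telescopic onset finds a noiseless step at the exact bin edge", {
  # baseline: Poisson 20 Hz; response: one guaranteed spike per 10 ms bin
  # per trial from +100 ms to +400 ms (100 Hz deterministic)
  set.seed(41)
  n_tr <- 150
  events <- seq(30, by = 30, length.out = n_tr)
  spikes <- sort(unlist(lapply(events, function(e) {
    base <- runif(rpois(1, 20 * 10.5), e - 10.2, e + 0.3)
    resp <- e + seq(0.105, 0.395, by = 0.01)
    c(base, resp)
  })))
  psth <- bin_spikes(spikes, events, c(-10, 1), 0.1)
  band <- baseline_band(psth, 0.99)
  det <- detect_response(psth, band, c(0, 1))
  expect_equal(det$direction, "excited")
  coarse <- c(det$first_crossing_bin, det$first_crossing_bin + 0.1)
  onset <- telescopic_onset(spikes, events, coarse, "excited",
                            analysis_end = 1)
  expect_equal(onset, 0.10, tolerance = 1e-9)
  expect_gte(onset, 0)
})

test_that("telescopic onset is absent without a 3-bin run", {
  # flat unit: coarse crossing forced artificially, no run exists
  set.seed(42)
  events <- seq(30, by = 30, length.out = 50)
  spikes <- sort(unlist(lapply(events, function(e)
    runif(rpois(1, 10 * 11), e - 10, e + 1))))
  onset <- telescopic_onset(spikes, events, c(0.5, 0.6), "excited",
                            analysis_end = 1)
  expect_true(is.na(onset))
})

test_that("the offset rule requires 300 ms back inside the band", {
  # fabricated 10 ms trace: baseline 5 Hz, response 50 Hz on [0.1, 0.4)
  rates <- c(rep(5, 1000), rep(5, 10), rep(50, 30), rep(5, 60))
  psth <- fake_psth(rates, 0.01, -10)
  band <- list(lo = 2, hi = 8, unclassifiable = FALSE)
  expect_equal(response_offset(psth, band, 0.10), 0.40)
  # sustained to window end -> absent
  rates2 <- c(rep(5, 1000), rep(5, 10), rep(50, 90))
  expect_true(is.na(response_offset(fake_psth(rates2, 0.01, -10), band, 0.10)))
  # 100 ms re-entry does not qualify; offset lands after the re-crossing
  rates3 <- c(rep(5, 1000), rep(5, 10), rep(50, 20), rep(5, 10),
              rep(50, 20), rep(5, 40))
  expect_equal(response_offset(fake_psth(rates3, 0.01, -10), band, 0.10), 0.60)
})

test_that("offset matches a brute-force scan oracle on random traces", {
  offset_oracle <- function(inside, edges, onset) {
    after <- which(edges > onset + 1e-9)
    for (i in after) {
      if (i + 29 <= length(inside) && all(inside[i:(i + 29)]))
        return(edges[i])
    }
    NA_real_
  }
  set.seed(77)
  for (rep in 1:30) {
    rates <- ifelse(runif(1100) < 0.3, 20, 5)   # in-band value 5, out 20
    psth <- fake_psth(rates, 0.01, -10)
    band <- list(lo = 0, hi = 10, unclassifiable = FALSE)
    edges <- psth$bin_edges[-length(psth$bin_edges)]
    expect_identical(response_offset(psth, band, 0),
                     offset_oracle(rates <= 10, edges, 0))
  }
})

test_that("signed-rank classification matches analytic extremes", {
  x <- c(10, 11, 12, 13, 14, 15)
  r0 <- signrank_direction(x, x)
  expect_equal(r0$direction, "none")
  expect_equal(r0$p, 1)
  # 30 trials, every post > baseline: exact two-sided minimum 2 * 2^-30
  set.seed(19)
  base <- runif(30, 5, 10)
  post <- base + runif(30, 0.5, 2)
  r1 <- signrank_direction(post, base)
  expect_equal(r1$direction, "excited")
  expect_equal(r1$p, 2 * 2^-30, tolerance = 1e-12)
  r2 <- signrank_direction(base, post)
  expect_equal(r2$direction, "inhibited")
})

test_that("simulated inhibitions are classified at amplitude lambda0/2", {
  hits <- 0
  for (s in 1:20) {
    beh <- make_behavior(s, n_reward = 60, n_control = 0)
    up <- unit_gen_params(baseline_rate = 10, response_kind = "inhibited",
                          response_amplitude = 5, response_onset = 0,
                          response_duration = 0.5)
    sp <- generate_unit_spikes(up, beh$trials, beh$session_duration, s + 900,
                               latencies = beh$latencies)
    ev <- beh$trials$cue_onset
    r <- signrank_direction(window_rates(sp, ev, c(0, 0.3)),
                            window_rates(sp, ev, c(-10, 0)))
    if (r$direction == "inhibited") hits <- hits + 1
  }
  expect_gte(hits, 18)   # >= 90% of seeds
})

test_that("rank-sum comparison matches exact enumeration", {
  r <- ranksum_compare(c(10, 11, 12), c(1, 2, 3))
  # oracle: all choose(6,3) = 20 arrangements; observed rank sum is extreme
  pool <- c(10, 11, 12, 1, 2, 3)
  sums <- apply(combn(6, 3), 2, function(ix) sum(rank(pool)[ix]))
  obs <- sum(rank(pool)[1:3])
  p_exact <- 2 * mean(sums >= obs)
  expect_equal(p_exact, 0.1)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_equal(r$direction, "a_higher")
  same <- ranksum_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p, 0.99)
})

test_that("a rate shift of lambda0 is detected by rank sum at 50 trials", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s + 1300)
    a <- rpois(50, 3) / 0.3        # 10 Hz window counts
    b <- rpois(50, 6) / 0.3        # shifted by lambda0
    if (ranksum_compare(b, a)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 19)
})
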