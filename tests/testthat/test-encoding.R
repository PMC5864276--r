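# Encoding measures: windowed rates, ROC/auROC, latency correlations,
# shuffled-latency nulls, sliding windows, kinematic encoding.

test_that("window_rates uses half-open windows and Hz units", {
  expect_equal(window_rates(c(10.05, 10.1, 10.2), 10, c(0, 0.3)), 10)
  expect_equal(window_rates(numeric(0), 10, c(0, 0.3)), 0)
  # [0.09, 0.30): spike at 0.09 included, at 0.30 excluded
  expect_equal(window_rates(c(10.09, 10.30), 10, c(0.09, 0.30)),
               1 / 0.21)
})

test_that("auROC matches closed forms and the pairwise oracle", {
  set.seed(2)
  x <- rpois(20, 5)
  expect_equal(auroc(x, x), 0.5)
  expect_equal(auroc(c(5, 6, 7), c(1, 2, 3)), 1.0)
  # pos=[2,3], neg=[1,2]: wins 3, tie 1 of 4 pairs -> 3.5/4
  expect_equal(auroc(c(2, 3), c(1, 2)), 0.875)
  rc <- roc_curve(c(2, 3), c(1, 2))
  expect_true(all(diff(rc$tpr) <= 0) || all(diff(rc$tpr) >= 0))
  expect_equal(min(rc$fpr), 0)
  expect_equal(max(rc$fpr), 1)
})

test_that("auROC is tie-symmetric and equals tie-corrected U/(n1 n2)", {
  set.seed(8)
  for (i in 1:50) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    pos <- rpois(n1, 4); neg <- rpois(n2, 4)
    a <- auroc(pos, neg)
    expect_equal(a + auroc(neg, pos), 1, tolerance = 1e-9)
    u_tie <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(a, u_tie, tolerance = 1e-9)
  }
})

test_that("control auROC is deterministic and centered on 0.5", {
  set.seed(30)
  events <- seq(30, by = 25, length.out = 40)
  spikes <- sort(runif(rpois(1, 10 * 1100), 0, 1100))
  c1 <- control_auroc(spikes, events, 0.3, seed = 4)
  c2 <- control_auroc(spikes, events, 0.3, seed = 4)
  expect_identical(c1, c2)
  expect_gte(abs(c1$window_a[1] - c1$window_b[1]), 0.3)  # disjoint
  reps <- vapply(1:200, function(s)
    control_auroc(spikes, events, 0.3, seed = s)$auroc, numeric(1))
  expect_lt(abs(mean(reps) - 0.5), 0.02)
  expect_error(control_auroc(spikes, events, 6), "too short")
})

test_that("Spearman correlation matches hand-computed rank values", {
  r1 <- latency_correlation(c(5, 4, 3, 2, 1), c(1, 2, 3, 4, 5))
  expect_equal(r1$rho, -1)
  expect_true(r1$significant)
  # ties: rates (1,1,2) vs latencies (3,2,1): Pearson on average ranks
  r2 <- latency_correlation(c(1, 1, 2), c(3, 2, 1), min_trials = 3)
  expect_equal(r2$rho, -sqrt(3) / 2, tolerance = 1e-9)
  # relabeling invariance: permuting trials jointly leaves rho unchanged
  set.seed(3)
  rates <- rpois(20, 5); lat <- rlnorm(20)
  perm <- sample(20)
  expect_equal(latency_correlation(rates, lat)$rho,
               latency_correlation(rates[perm], lat[perm])$rho)
  # too few trials -> not evaluated
  expect_false(latency_correlation(c(1, 2), c(1, 2))$evaluated)
})

test_that("latency correlation type-I error is near alpha on null data", {
  set.seed(60)
  sig <- vapply(1:600, function(i) {
    u <- make_null_unit(25)
    latency_correlation(u$rates, u$latencies)$significant
  }, logical(1))
  expect_lt(abs(mean(sig) - 0.05), 0.025)
})

test_that("shuffle null is reproducible and separates real coupling", {
  set.seed(90)
  null_units <- lapply(1:60, function(i) make_null_unit(25))
  s1 <- shuffle_null(null_units, n_iter = 300, seed = 5)
  s2 <- shuffle_null(null_units, n_iter = 300, seed = 5)
  expect_identical(s1, s2)
  # null population: observed count inside the null's central 95%
  qs <- quantile(s1$null_sig_counts, c(0.025, 0.975))
  expect_gte(s1$observed$sig_count, qs[1])
  expect_lte(s1$observed$sig_count, qs[2])
  # coupled population: rates built from the latency ranks
  coupled <- lapply(1:60, function(i) {
    lat <- rlnorm(25, log(1.5), 0.6)
    g <- exp(-0.8 * qnorm((rank(lat) - 0.5) / 25))
    list(rates = rpois(25, 3 + 3.75 * g) / 0.3, latencies = lat)
  })
  sc <- shuffle_null(coupled, n_iter = 300, seed = 6)
  expect_gt(sc$observed$sig_count, max(sc$null_sig_counts))
  expect_lt(sc$observed$mean_rho, min(sc$null_mean_rho))
  expect_gt(mean(sc$exceeds_shuffle), mean(s1$exceeds_shuffle))
})

test_that("per-unit shuffle rho agrees with direct cor.test on ranks", {
  set.seed(14)
  u <- make_null_unit(20)
  s <- shuffle_null(list(u), n_iter = 50, seed = 2)
  direct <- suppressWarnings(
    cor.test(u$rates, u$latencies, method = "spearman", exact = FALSE))
  expect_equal(s$observed$rho[1], unname(direct$estimate), tolerance = 1e-12)
})

test_that("sliding windows stay null without coupling and flag a +50 ms change", {
  set.seed(70)
  n_tr <- 30
  events <- seq(30, by = 25, length.out = n_tr)
  lat <- rlnorm(n_tr, log(1.5), 0.6)
  mk_unit <- function(coupled) {
    # spikes on [-1, 1.5) around each event; coupling only from +50 ms on
    unlist(lapply(seq_len(n_tr), function(i) {
      g <- if (coupled) exp(-1.2 * qnorm((rank(lat)[i] - 0.5) / n_tr)) else 1
      base <- runif(rpois(1, 10 * 2.5), events[i] - 1, events[i] + 1.5)
      extra <- runif(rpois(1, 20 * g * 0.95), events[i] + 0.05,
                     events[i] + 1)
      sort(c(base, extra))
    }))
  }
  null_units <- lapply(1:40, function(j) mk_unit(FALSE))
  sw0 <- sliding_window_series(null_units, events, lat, n_perm = 400,
                               seed = 3)
  expect_equal(length(sw0$window_starts), 30)
  expect_lt(abs(mean(sw0$mean_rho)), 0.05)
  expect_lte(sum(sw0$flagged), 3)
  cu <- lapply(1:40, function(j) mk_unit(TRUE))
  sw1 <- sliding_window_series(cu, events, lat, n_perm = 400, seed = 3)
  expect_false(is.na(sw1$first_flagged_window))
  expect_gte(sw1$first_flagged_window, 0.05 - 1e-9)
})

test_that("pre-cue state coupling flags pre-cue windows", {
  set.seed(71)
  n_tr <- 30
  events <- seq(30, by = 25, length.out = n_tr)
  lat <- rlnorm(n_tr, log(1.5), 0.6)
  units <- lapply(1:40, function(j) {
    unlist(lapply(seq_len(n_tr), function(i) {
      g <- exp(-1.2 * qnorm((rank(lat)[i] - 0.5) / n_tr))
      sort(runif(rpois(1, 10 * g * 2.5), events[i] - 1, events[i] + 1.5))
    }))
  })
  sw <- sliding_window_series(units, events, lat, n_perm = 400, seed = 9)
  expect_false(is.na(sw$first_flagged_window))
  expect_lt(sw$first_flagged_window, 0)
})

test_that("kinematic encoding handles coupling, null and degenerate inputs", {
  set.seed(55)
  n <- 30
  lat <- rlnorm(n, log(1.5), 0.6)
  dist <- runif(n, 5, 30)
  kin <- data.frame(distance = dist, vel_early = runif(n, 0, 10),
                    vel_late = runif(n, 0, 10),
                    move_onset = pmax(lat - 0.4, 0.05))
  # unit whose gain rises for short latency AND short distance
  both <- exp(-0.6 * qnorm((rank(lat) - 0.5) / n)) *
          exp(-0.6 * qnorm((rank(dist) - 0.5) / n))
  rates <- rpois(n, 3 + 4 * both) / 0.3
  ke <- kinematic_encoding(rates, kin)
  expect_lt(ke$distance$rho, 0)
  # gamma = 0 population: mean distance-rho near 0
  rhos <- vapply(1:400, function(j) {
    r <- rpois(n, 3) / 0.3
    kinematic_encoding(r, kin)$distance$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.035)
  # constant distance -> not evaluated
  kin2 <- kin; kin2$distance <- rep(10, n)
  expect_false(kinematic_encoding(rates, kin2)$distance$evaluated)
})

test_that("latency-rho and distance-rho correlate across coupled units", {
  set.seed(56)
  n <- 25
  lat <- rlnorm(n, log(1.5), 0.6)
  dist <- runif(n, 5, 30)
  kin <- data.frame(distance = dist, vel_early = runif(n, 0, 10),
                    vel_late = runif(n, 0, 10), move_onset = lat - 0.2)
  res <- t(vapply(1:60, function(j) {
    beta <- runif(1, 0, 1.2)   # heterogeneous coupling strength
    g <- exp(-beta * qnorm((rank(lat) - 0.5) / n)) *
         exp(-beta * qnorm((rank(dist) - 0.5) / n))
    rates <- rpois(n, 3 + 4 * g) / 0.3
    c(latency_correlation(rates, lat)$rho,
      kinematic_encoding(rates, kin)$distance$rho)
  }, numeric(2)))
  expect_gt(cor(res[, 1], res[, 2], method = "spearman"), 0.3)
})
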