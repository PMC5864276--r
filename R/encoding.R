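# Per-unit encoding measures: ROC discrimination, trial-by-trial
# firing-latency Spearman correlations with shuffled-latency nulls,
# sliding-window correlation series, kinematic-encoding correlations.

#' Per-trial firing rates in a window
#'
#' @param spikes spike times (s).
#' @param event_times alignment events (s).
#' @param window numeric length-2 `[a, b)` relative to the event.
#' @return Numeric vector of rates (Hz), one per event.
#' @export
window_rates <- function(spikes, event_times, window) {
  w <- window[2] - window[1]
  vapply(event_times, function(e)
    count_in_window(spikes, e + window[1], e + window[2]) / w, numeric(1))
}

#' ROC curve and auROC between two rate distributions
#'
#' Sweeps criteria from zero to the maximum rate; a trial is called
#' positive when its rate is at or above the criterion. The true-positive
#' rate (fraction of `pos` above criterion) is plotted against the
#' false-positive rate (fraction of `neg` above criterion) and the area is
#' taken by the trapezoidal rule, which equals the tie-corrected
#' Mann-Whitney U / (n1 * n2).
#'
#' @param pos,neg numeric vectors of per-trial rates (Hz).
#' @return List: `thresholds`, `tpr`, `fpr`, `auroc`.
#' @export
roc_curve <- function(pos, neg) {
  stopifnot(length(pos) > 0, length(neg) > 0)
  mx <- max(pos, neg)
  th <- sort(unique(c(0, pos, neg, mx + 1)))
  tpr <- vapply(th, function(cr) mean(pos >= cr), numeric(1))
  fpr <- vapply(th, function(cr) mean(neg >= cr), numeric(1))
  # thresholds ascend, so fpr/tpr descend from (1,1) to (0,0)
  a <- sum(diff(-fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(thresholds = th, tpr = tpr, fpr = fpr, auroc = a)
}

#' Area under the ROC curve
#'
#' @inheritParams roc_curve
#' @return auROC in [0, 1]; 0.5 means no discrimination.
#' @export
auroc <- function(pos, neg) roc_curve(pos, neg)$auroc

#' Control auROC from two random baseline windows
#'
#' Discrimination between per-trial rates of two disjoint, randomly placed
#' baseline windows of the analysis-window width; its distribution centers
#' on 0.5 for a stationary unit and anchors the test auROC distributions.
#'
#' @param spikes,event_times as in [window_rates()].
#' @param width analysis-window width (s).
#' @param baseline_window numeric length-2, default `c(-10, 0)`.
#' @param seed integer seed for the window draw.
#' @return List: `auroc`, `window_a`, `window_b`.
#' @export
control_auroc <- function(spikes, event_times, width,
                          baseline_window = c(-10, 0), seed = 1) {
  span <- baseline_window[2] - baseline_window[1]
  if (span < 2 * width) stop("baseline too short for two disjoint windows")
  with_seed(seed, {
    repeat {
      s <- stats::runif(2, baseline_window[1], baseline_window[2] - width)
      if (abs(s[1] - s[2]) >= width) break
    }
    wa <- c(s[1], s[1] + width); wb <- c(s[2], s[2] + width)
    list(auroc = auroc(window_rates(spikes, event_times, wa),
                       window_rates(spikes, event_times, wb)),
         window_a = wa, window_b = wb)
  })
}

# Spearman rho via Pearson on average ranks, plus the t-approximation
# p-value; used by the vectorized shuffle machinery.
spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  den <- sqrt(sum(cx^2) * sum(cy^2))
  if (den == 0) return(NA_real_)
  sum(cx * cy) / den
}

spearman_p_approx <- function(rho, n) {
  if (is.na(rho) || n < 3) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tt), n - 2)
}

#' Trial-by-trial firing-latency Spearman correlation
#'
#' Spearman rank correlation (average ranks for ties) between per-trial
#' firing rates and port-entry latencies, over responded trials only. The
#' two-sided p-value is exact for n <= 9 without ties and uses the
#' t-approximation otherwise.
#'
#' @param rates per-trial firing rates (Hz).
#' @param latencies per-trial latencies (s); `NA` = not responded.
#' @param alpha significance level.
#' @param min_trials minimum responded trials to evaluate (default 5).
#' @return List: `rho`, `p`, `n`, `significant`, `evaluated`.
#' @export
latency_correlation <- function(rates, latencies, alpha = 0.05,
                                min_trials = 5) {
  keep <- !is.na(latencies) & !is.na(rates)
  r <- rates[keep]; l <- latencies[keep]
  n <- length(r)
  if (n < min_trials)
    return(list(rho = NA_real_, p = NA_real_, n = n, significant = FALSE,
                evaluated = FALSE))
  if (stats::sd(r) == 0 || stats::sd(l) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, significant = FALSE,
                evaluated = FALSE))
  use_exact <- n <= 9 && !anyDuplicated(r) && !anyDuplicated(l)
  ct <- suppressWarnings(
    stats::cor.test(r, l, method = "spearman", exact = use_exact))
  rho <- unname(ct$estimate)
  p <- if (use_exact) ct$p.value else spearman_p_approx(rho, n)
  list(rho = rho, p = p, n = n, significant = isTRUE(p < alpha),
       evaluated = TRUE)
}

#' Shuffled-latency permutation null for a unit population
#'
#' For each of `n_iter` iterations the trial latencies of every unit are
#' independently permuted and the firing-latency Spearman correlation is
#' recomputed; the null records, per iteration, the number of significant
#' units (p < alpha, t-approximation) and the population mean rho. A unit
#' "exceeds shuffle" when its observed |rho| is above the 95th percentile
#' of its own shuffled |rho| distribution.
#'
#' @param units list; each element a list with numeric `rates` and
#'   `latencies` (same length, `NA` latency = not responded).
#' @param n_iter shuffle iterations, default 1000.
#' @param alpha significance level.
#' @param seed integer seed.
#' @param min_trials minimum responded trials per unit.
#' @return List: `observed` (per-unit rho/p/significant, `sig_count`,
#'   `mean_rho`), `null_sig_counts`, `null_mean_rho` (length `n_iter`),
#'   `exceeds_shuffle`, `shuffle_q95`, `count_percentile`.
#' @export
shuffle_null <- function(units, n_iter = 1000, alpha = 0.05, seed = 1,
                         min_trials = 5) {
  nu <- length(units)
  rho_obs <- p_obs <- rep(NA_real_, nu)
  eval_ok <- logical(nu)
  prep <- vector("list", nu)
  for (j in seq_len(nu)) {
    u <- units[[j]]
    keep <- !is.na(u$latencies) & !is.na(u$rates)
    r <- u$rates[keep]; l <- u$latencies[keep]
    n <- length(r)
    if (n < min_trials || stats::sd(r) == 0 || stats::sd(l) == 0) next
    cx <- rank(r) - (n + 1) / 2
    cy <- rank(l) - (n + 1) / 2
    den <- sqrt(sum(cx^2) * sum(cy^2))
    rho_obs[j] <- sum(cx * cy) / den
    p_obs[j] <- spearman_p_approx(rho_obs[j], n)
    eval_ok[j] <- TRUE
    prep[[j]] <- list(cx = cx, cy = cy, den = den, n = n)
  }
  null_rho <- matrix(NA_real_, nrow = n_iter, ncol = nu)
  with_seed(seed, {
    for (j in which(eval_ok)) {
      pj <- prep[[j]]
      # permuting the centered rate ranks against fixed latency ranks is
      # equivalent to shuffling the latencies
      null_rho[, j] <- vapply(seq_len(n_iter), function(k)
        sum(sample(pj$cx) * pj$cy) / pj$den, numeric(1))
    }
  })
  nvec <- vapply(prep, function(p) if (is.null(p)) NA_real_ else p$n,
                 numeric(1))
  null_p <- null_rho
  for (j in which(eval_ok)) {
    rr <- null_rho[, j]
    tt <- rr * sqrt((nvec[j] - 2) / pmax(1 - rr^2, 1e-12))
    null_p[, j] <- 2 * stats::pt(-abs(tt), nvec[j] - 2)
  }
  sig_obs <- !is.na(p_obs) & p_obs < alpha
  null_sig_counts <- rowSums(null_p < alpha, na.rm = TRUE)
  null_mean_rho <- rowMeans(null_rho, na.rm = TRUE)
  q95 <- rep(NA_real_, nu)
  q95[eval_ok] <- apply(abs(null_rho[, eval_ok, drop = FALSE]), 2,
                        stats::quantile, 0.95, names = FALSE)
  exceeds <- !is.na(rho_obs) & abs(rho_obs) > q95
  obs_count <- sum(sig_obs)
  list(observed = list(rho = rho_obs, p = p_obs, significant = sig_obs,
                       sig_count = obs_count,
                       mean_rho = mean(rho_obs, na.rm = TRUE)),
       null_sig_counts = null_sig_counts,
       null_mean_rho = null_mean_rho,
       exceeds_shuffle = exceeds,
       shuffle_q95 = q95,
       count_percentile = mean(null_sig_counts < obs_count) +
         0.5 * mean(null_sig_counts == obs_count))
}

#' Sliding-window firing-latency correlation series
#'
#' Spearman correlations between firing and port-entry latency in 50 ms
#' windows from 0.5 s before to 1 s after the cue (30 windows). Each
#' window's population mean rho is compared against a permutation null
#' (latencies shuffled per unit, `n_perm` label shuffles); the first
#' flagged window marks where latency encoding departs from the pre-cue
#' state.
#'
#' @param spike_list list of spike-time vectors, one per unit.
#' @param event_times cue-onset times (s), one per trial.
#' @param latencies per-trial latencies (s, `NA` = not responded).
#' @param alpha significance level for per-unit window correlations.
#' @param n_perm permutation count, default 1000.
#' @param seed integer seed.
#' @param win_width,win_start,win_end series geometry (s), defaults 0.05,
#'   -0.5, 1.
#' @param min_trials minimum responded trials.
#' @param flag_level per-window permutation level for flagging departures;
#'   the default 0.002 keeps the family-wise false-flag rate over the 30
#'   windows near 5%.
#' @return List: `window_starts`, `mean_rho`, `frac_sig_neg`,
#'   `frac_sig_pos`, `perm_p` (per-window two-sided permutation p),
#'   `null_lo`, `null_hi` (central-95% band of the null mean rho),
#'   `flagged`, `first_flagged_window` (start time, s, or `NA`).
#' @export
sliding_window_series <- function(spike_list, event_times, latencies,
                                  alpha = 0.05, n_perm = 1000, seed = 1,
                                  win_width = 0.05, win_start = -0.5,
                                  win_end = 1, min_trials = 5,
                                  flag_level = 0.002) {
  starts <- seq(win_start, win_end - win_width / 2, by = win_width)
  nw <- length(starts)
  keep <- !is.na(latencies)
  ev <- event_times[keep]; lat <- latencies[keep]
  n <- length(ev)
  if (n < min_trials) stop("fewer responded trials than min_trials")
  cy <- rank(lat) - (n + 1) / 2
  deny <- sqrt(sum(cy^2))
  nu <- length(spike_list)
  # per unit: nw x n matrix of centered rate ranks, row-normalized
  mats <- vector("list", nu)
  rho_mat <- matrix(NA_real_, nw, nu)
  for (j in seq_len(nu)) {
    rr <- matrix(0, nw, n)
    for (w in seq_len(nw)) {
      rates <- window_rates(spike_list[[j]], ev,
                            c(starts[w], starts[w] + win_width))
      cr <- rank(rates) - (n + 1) / 2
      dx <- sqrt(sum(cr^2))
      rr[w, ] <- if (dx > 0) cr / dx else 0
    }
    mats[[j]] <- rr
    rho_mat[, j] <- as.numeric(rr %*% cy) / deny
  }
  p_mat <- 2 * stats::pt(-abs(rho_mat * sqrt((n - 2) /
                                pmax(1 - rho_mat^2, 1e-12))), n - 2)
  mean_rho <- rowMeans(rho_mat)
  null_mean <- matrix(0, n_perm, nw)
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      acc <- numeric(nw)
      for (j in seq_len(nu)) {
        perm_cy <- sample(cy)
        acc <- acc + as.numeric(mats[[j]] %*% perm_cy) / deny
      }
      null_mean[k, ] <- acc / nu
    }
  })
  lo <- apply(null_mean, 2, stats::quantile, 0.025, names = FALSE)
  hi <- apply(null_mean, 2, stats::quantile, 0.975, names = FALSE)
  perm_p <- vapply(seq_len(nw), function(w)
    (1 + sum(abs(null_mean[, w]) >= abs(mean_rho[w]))) / (1 + n_perm),
    numeric(1))
  # never demand a p below the permutation resolution
  flagged <- perm_p <= pmax(flag_level, 1 / (n_perm + 1) + 1e-12)
  list(window_starts = starts,
       mean_rho = mean_rho,
       frac_sig_neg = rowMeans(p_mat < alpha & rho_mat < 0),
       frac_sig_pos = rowMeans(p_mat < alpha & rho_mat > 0),
       perm_p = perm_p,
       null_lo = lo, null_hi = hi, flagged = flagged,
       first_flagged_window = if (any(flagged)) starts[which(flagged)[1]]
                              else NA_real_)
}

#' Kinematic-encoding correlations for one unit
#'
#' Spearman correlations between per-trial firing rates and four movement
#' variables: distance from the port at cue onset (cm), mean velocity 0 to
#' 0.5 s and 0.5 to 1 s post-cue (cm/s), and movement-onset latency (s).
#' Variables with zero variance or too few defined trials are flagged
#' not-evaluated.
#'
#' @param rates per-trial firing rates (Hz).
#' @param kin data.frame with columns `distance`, `vel_early`, `vel_late`,
#'   `move_onset` (one row per trial; `NA` allowed).
#' @param alpha significance level.
#' @param min_trials minimum defined trials per variable.
#' @return Named list of [latency_correlation()]-shaped results.
#' @export
kinematic_encoding <- function(rates, kin, alpha = 0.05, min_trials = 5) {
  vars <- c("distance", "vel_early", "vel_late", "move_onset")
  stopifnot(all(vars %in% names(kin)))
  out <- lapply(vars, function(v)
    latency_correlation(rates, kin[[v]], alpha = alpha,
                        min_trials = min_trials))
  names(out) <- vars
  out
}
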