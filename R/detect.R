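# Event-response detection and classification.
#
# A unit is called excited/inhibited for an event when at least one
# analysis-window bin of its PSTH (at the unit's deflection-point bin size)
# falls outside the 99% band of the baseline bin rates. Onsets are refined
# telescopically: within the first out-of-band coarse bin, the first run of
# three consecutive 10 ms bins beyond the 10 ms-resolution band marks the
# onset. The band is a tolerance band (mean +/- z * SD over baseline bin
# rates), not a SEM interval: single bins are compared against it, and a
# SEM interval would shrink with baseline length and flag nearly every bin.
# A SEM variant is available via `band_kind = "sem"`.

#' Baseline confidence band for bin rates
#'
#' @param psth a `vp_psth` covering the baseline (see [zscore_psth()]).
#' @param level band coverage, default 0.99 (detection); 0.95 is used for
#'   the kinematic reuse.
#' @param baseline_window numeric length-2, default `c(-10, 0)`.
#' @param band_kind "sd" (tolerance band over baseline bin rates, default)
#'   or "sem" (interval for the baseline mean).
#' @return List: `lo`, `hi` (Hz), `mean`, `sd`, `level`, `bin_size`,
#'   `unclassifiable` (TRUE when the baseline SD is zero).
#' @export
baseline_band <- function(psth, level = 0.99, baseline_window = c(-10, 0),
                          band_kind = c("sd", "sem")) {
  band_kind <- match.arg(band_kind)
  lo_edges <- psth$bin_edges[-length(psth$bin_edges)]
  base <- lo_edges >= baseline_window[1] - 1e-9 &
          lo_edges < baseline_window[2] - 1e-9
  rates <- psth$trial_mean_rate[base]
  m <- mean(rates)
  s <- stats::sd(rates)
  if (!is.finite(s) || s == 0)
    return(list(lo = NA_real_, hi = NA_real_, mean = m, sd = s,
                level = level, bin_size = psth$bin_size,
                unclassifiable = TRUE))
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- if (band_kind == "sd") z * s else z * s / sqrt(length(rates))
  list(lo = m - half, hi = m + half, mean = m, sd = s, level = level,
       bin_size = psth$bin_size, unclassifiable = FALSE)
}

#' Preliminary response direction by band crossing
#'
#' Excited when any analysis-window bin rate exceeds the band's upper
#' limit, inhibited when any falls below the lower limit; when bins cross
#' in both directions, the first crossing in time decides.
#'
#' @param psth a `vp_psth` covering the analysis window.
#' @param band a [baseline_band()].
#' @param analysis_window numeric length-2 relative to the event, default
#'   `c(0, 10)`.
#' @return List: `direction` ("excited" | "inhibited" | "none"),
#'   `first_crossing_bin` (left edge, s; `NA` when none).
#' @export
detect_response <- function(psth, band, analysis_window = c(0, 10)) {
  if (isTRUE(band$unclassifiable))
    return(list(direction = "unclassifiable", first_crossing_bin = NA_real_))
  lo_edges <- psth$bin_edges[-length(psth$bin_edges)]
  sel <- which(lo_edges >= analysis_window[1] - 1e-9 &
               lo_edges < analysis_window[2] - 1e-9)
  f <- psth$trial_mean_rate[sel]
  above <- f > band$hi
  below <- f < band$lo
  cross <- which(above | below)
  if (!length(cross))
    return(list(direction = "none", first_crossing_bin = NA_real_))
  first <- cross[1]
  list(direction = if (above[first]) "excited" else "inhibited",
       first_crossing_bin = lo_edges[sel[first]])
}

#' Telescopic onset refinement at 10 ms resolution
#'
#' Within the first out-of-band coarse bin, the spikes are re-binned at
#' 10 ms, the band is recomputed from the baseline at 10 ms bins, and the
#' onset is the left edge of the first 10 ms bin that begins a run of three
#' consecutive 10 ms bins beyond the band on the same side as the coarse
#' crossing. When no such run starts inside the coarse bin, the coarse
#' detection stands but the refined onset is reported absent (`NA`).
#'
#' @param spikes,event_times as in [bin_spikes()].
#' @param coarse_bin numeric length-2: the first crossing coarse bin
#'   `[start, end)` in seconds relative to the event.
#' @param direction "excited" or "inhibited" (side of the crossing).
#' @param level band coverage (default 0.99).
#' @param analysis_end right edge (s) of the analysis window; the run may
#'   extend past the coarse bin up to this edge.
#' @param baseline_window numeric length-2, default `c(-10, 0)`.
#' @return Onset in seconds relative to the event, or `NA_real_`.
#' @export
telescopic_onset <- function(spikes, event_times, coarse_bin, direction,
                             level = 0.99, analysis_end = NULL,
                             baseline_window = c(-10, 0)) {
  fine <- 0.01
  end <- analysis_end %||% coarse_bin[2]
  end <- max(end, coarse_bin[2])
  # snap the full [baseline, end) span to 10 ms bins
  span_end <- ceiling((end - baseline_window[1]) / fine - 1e-9) * fine +
    baseline_window[1]
  psth10 <- bin_spikes(spikes, event_times, c(baseline_window[1], span_end),
                       fine)
  band10 <- baseline_band(psth10, level = level,
                          baseline_window = baseline_window)
  if (isTRUE(band10$unclassifiable)) return(NA_real_)
  lo_edges <- psth10$bin_edges[-length(psth10$bin_edges)]
  f <- psth10$trial_mean_rate
  beyond <- if (direction == "excited") f > band10$hi else f < band10$lo
  start_ok <- which(lo_edges >= coarse_bin[1] - 1e-9 &
                    lo_edges < coarse_bin[2] - 1e-9)
  for (i in start_ok) {
    if (i + 2 <= length(beyond) && all(beyond[i:(i + 2)]))
      return(lo_edges[i])
  }
  NA_real_
}

#' Response offset from the 10 ms-resolution trace
#'
#' The offset is the start time of the first 10 ms bin after the onset from
#' which the trial-mean rate stays inside the band contiguously for at
#' least 300 ms. A shorter re-entry does not qualify; a response sustained
#' to the end of the window has no offset (`NA`).
#'
#' @param psth10 `vp_psth` at 10 ms bins covering baseline and analysis
#'   window.
#' @param band10 the matching [baseline_band()].
#' @param onset onset time (s) as returned by [telescopic_onset()].
#' @return Offset in seconds relative to the event, or `NA_real_`.
#' @export
response_offset <- function(psth10, band10, onset) {
  if (is.na(onset)) return(NA_real_)
  lo_edges <- psth10$bin_edges[-length(psth10$bin_edges)]
  f <- psth10$trial_mean_rate
  inside <- f >= band10$lo & f <= band10$hi
  need <- as.integer(round(0.3 / psth10$bin_size))
  cand <- which(lo_edges > onset + 1e-9)
  for (i in cand) {
    if (i + need - 1 <= length(inside) && all(inside[i:(i + need - 1)]))
      return(lo_edges[i])
  }
  NA_real_
}

#' Full response profile: direction, telescopically confirmed onset, offset
#'
#' Runs [detect_response()] and then attempts telescopic onset refinement,
#' iterating over the out-of-band bins (same side as the first crossing, in
#' time order) until one contains a confirmed 3-bin run at 10 ms
#' resolution. Iterating protects the onset estimate from an isolated
#' noise bin earlier in the window: such a bin cannot produce a 10 ms run,
#' while the true response can. When no crossing confirms, the coarse
#' direction stands with an absent onset.
#'
#' @inheritParams telescopic_onset
#' @param psth coarse-bin `vp_psth` covering baseline and analysis window.
#' @param band the matching [baseline_band()].
#' @param analysis_window numeric length-2 relative to the event.
#' @return List: `direction`, `onset`, `offset`, `crossing_bin` (left edge
#'   of the confirming coarse bin, else the first crossing).
#' @export
response_onset_profile <- function(spikes, event_times, psth, band,
                                   analysis_window = c(0, 10), level = 0.99,
                                   baseline_window = c(-10, 0)) {
  det <- detect_response(psth, band, analysis_window)
  out <- list(direction = det$direction, onset = NA_real_, offset = NA_real_,
              crossing_bin = det$first_crossing_bin)
  if (det$direction %in% c("none", "unclassifiable")) return(out)
  lo_edges <- psth$bin_edges[-length(psth$bin_edges)]
  sel <- lo_edges >= analysis_window[1] - 1e-9 &
         lo_edges < analysis_window[2] - 1e-9
  f <- psth$trial_mean_rate
  beyond <- if (det$direction == "excited") f > band$hi else f < band$lo
  for (edge in lo_edges[sel & beyond]) {
    onset <- telescopic_onset(spikes, event_times,
                              c(edge, edge + psth$bin_size),
                              det$direction, level = level,
                              analysis_end = analysis_window[2],
                              baseline_window = baseline_window)
    if (!is.na(onset)) {
      out$onset <- onset
      out$crossing_bin <- edge
      break
    }
  }
  if (!is.na(out$onset)) {
    span_end <- baseline_window[1] +
      ceiling((analysis_window[2] - baseline_window[1]) / 0.01 - 1e-9) * 0.01
    psth10 <- bin_spikes(spikes, event_times,
                         c(baseline_window[1], span_end), 0.01)
    band10 <- baseline_band(psth10, level = level,
                            baseline_window = baseline_window)
    if (!isTRUE(band10$unclassifiable))
      out$offset <- response_offset(psth10, band10, out$onset)
  }
  out
}

#' Response direction by Wilcoxon signed rank
#'
#' Two-sided paired signed-rank test of per-trial firing in the 300 ms
#' post-event window against per-trial baseline firing; the direction is
#' the sign of the median paired difference when p < alpha. Zero
#' differences are dropped (Wilcoxon convention); identical samples give
#' direction "none" with p = 1.
#'
#' @param post_rates,baseline_rates per-trial rates (Hz), paired by trial.
#' @param alpha significance level, default 0.05.
#' @return List: `direction`, `p`, `median_diff`.
#' @export
signrank_direction <- function(post_rates, baseline_rates, alpha = 0.05) {
  stopifnot(length(post_rates) == length(baseline_rates))
  d <- post_rates - baseline_rates
  if (all(d == 0))
    return(list(direction = "none", p = 1, median_diff = 0))
  p <- suppressWarnings(
    stats::wilcox.test(post_rates, baseline_rates, paired = TRUE)$p.value)
  md <- stats::median(d)
  dir <- if (p < alpha) {
    if (md > 0) "excited" else if (md < 0) "inhibited" else "none"
  } else "none"
  list(direction = dir, p = p, median_diff = md)
}

#' Compare event-related firing between two trial sets (rank sum)
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test; used for reward-cue
#' versus control-cue and responded versus non-responded contrasts.
#'
#' @param rates_a,rates_b per-trial rates (Hz) for the two trial sets.
#' @return List: `p`, `direction` ("a_higher" | "b_higher" | "none" by
#'   median comparison), `median_a`, `median_b`.
#' @export
ranksum_compare <- function(rates_a, rates_b) {
  stopifnot(length(rates_a) >= 3, length(rates_b) >= 3)
  p <- suppressWarnings(stats::wilcox.test(rates_a, rates_b)$p.value)
  ma <- stats::median(rates_a); mb <- stats::median(rates_b)
  list(p = p,
       direction = if (ma > mb) "a_higher" else if (mb > ma) "b_higher" else "none",
       median_a = ma, median_b = mb)
}
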