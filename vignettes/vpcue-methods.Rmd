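---
title: "Methods: cue-response encoding analysis in vpcue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cue-response encoding analysis in vpcue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpcue)
```

## The scientific problem

Ventral pallidum (VP) neurons respond vigorously to reward-predictive
cues. The question this package's pipeline is built around is *what those
responses encode*: the learned value of the cue, the likelihood that the
animal will respond to it, or the vigor (latency) of the response — and
whether that depends on the task contingency. Two tasks generate
superficially similar behavior from different causal structures:

* **Instrumental (DS task).** An auditory discriminative stimulus (DS)
  lasts up to 10 s; a port entry during the cue delivers sucrose and
  terminates the cue. A control cue (NS) has no programmed consequence.
* **Pavlovian conditioning.** A 10 s CS+ is followed by sucrose 8 s after
  onset regardless of behavior; a CS− is never rewarded.

Both tasks use a pseudorandom ITI schedule with a 50 s mean, and animals
train to a criterion of entries on ≥ 70% of reward-cue and < 30% of
control-cue presentations (`criterion_met()`).

A session (`vp_session`) bundles the trial table, session-wide port-entry
times, one spike train per isolated unit, and optionally an overhead
tracking trace at 30 frames/s. All analysis windows are half-open
`[a, b)` seconds relative to cue onset; the baseline is the 10 s before
onset. Port entries are stored once per session and viewed per trial;
entries during reward consumption are retained but never counted as cue
responses. On instrumental trials terminated by the rewarded entry itself
the latency window closes at the offset so the terminating entry counts —
otherwise the half-open rule would exclude precisely the response that
defines the trial.

## PSTHs and bin-size selection

`bin_spikes()` builds trial × bin count matrices around events.
Per-unit bin size is chosen by AIC (`optimal_bin_size()`): the PSTH at bin
width $\Delta$ is treated as a piecewise-constant inhomogeneous-Poisson
rate model for the spike times, with log-likelihood

$$\mathcal{L}(\Delta) = \sum_j N_j \log\frac{N_j}{n\Delta} - N,$$

where $N_j$ is the pooled count in bin $j$, $n$ the trial count and $N$
the total count, and $\mathrm{AIC} = -2\mathcal{L} + 2k$ with $k$ the
number of bins. This likelihood is comparable across bin sizes: on
constant-rate data it is flat in $\Delta$ so the penalty favors coarse
bins, while a genuine transient rewards bins fine enough to resolve it. A
per-bin likelihood of the *counts* does not have this property — merging
bins always increases it, for any data — which is why the continuous-time
form is used. A spikeless train has $\mathrm{AIC} = 2k$ exactly.

Because the AIC drops quickly over small bins and then flattens, the bin
actually used is the **deflection point**: the smallest candidate whose
AIC is within 10% of the optimum. The 10% rule is inherently
scale-sensitive (the AIC carries an additive constant proportional to the
spike count and the logarithm of the time unit), so deflection values
should be compared only within one configuration; the rule's structural
behavior, not a particular population average, is what the tests pin
down. Candidates default to divisors of the analysis window between 10 ms
and 1 s. When the optimal AIC is non-positive the rule uses
$|\mathrm{AIC}_{opt}|$ in the denominator and the result carries an
`aic_negative` flag.

`zscore_psth()` z-scores each bin's trial-mean rate against the mean and
SD of the baseline bins at the same bin size; a zero baseline SD flags
the unit unclassifiable rather than substituting a floor.

## Response detection

`baseline_band()` sets a 99% **tolerance band** over baseline bin rates,
mean ± 2.576 SD. A SEM-based interval for the baseline *mean* would
shrink with baseline length and flag nearly every post-cue bin, because
single bins — not means — are compared against the band; the SEM variant
remains available via `band_kind = "sem"` for completeness.
`detect_response()` calls a preliminary excitation (inhibition) when any
analysis-window bin exceeds (falls below) the band, the first crossing in
time deciding when both occur.

Onsets are refined telescopically (`telescopic_onset()`): within an
out-of-band coarse bin, spikes are re-binned at 10 ms, the band is
recomputed from the baseline at 10 ms resolution, and the onset is the
left edge of the first 10 ms bin beginning a run of three consecutive
out-of-band bins on the same side. `response_onset_profile()` iterates
over the out-of-band coarse bins in time order until one confirms: an
isolated noise bin essentially never produces a 3 × 10 ms run, while a
genuine response does, so iteration immunizes the onset estimate against
stray crossings earlier in the window. When no bin confirms, the coarse
detection stands with an absent onset. The offset
(`response_offset()`) is the start of the first 10 ms bin after onset
from which firing stays inside the band for at least 300 ms contiguously;
a response sustained to the end of the window has no offset.

Because a per-bin 99% band over a 10 s window at fine bins inevitably
crosses somewhere on pure noise, the per-bin crossings are deliberately
left uncorrected (matching the single-bin trigger rule) and the unit's
reported **response class** rests on a single paired test:
`signrank_direction()`, a two-sided Wilcoxon signed rank of per-trial
firing in the 300 ms post-cue window against the 10 s baseline, direction
by the sign of the median difference. A band crossing promotes a unit
beyond the sign-rank verdict only when telescopically confirmed (this
catches responses outside the 300 ms classification window). The test
suite verifies that this rule leaves unmodulated units unclassified
while recovering generated excitations and inhibitions with the correct
sign. Zero differences are dropped (Wilcoxon convention); `wilcox.test()`'s
standard exact/approximate switch is used. Event contrasts
(reward vs control cue, responded vs non-responded trials) use two-sided
rank-sum tests (`ranksum_compare()`).

## ROC discrimination

`roc_curve()` sweeps criteria from zero to the unit's maximum rate,
calling a trial positive when its rate is at or above the criterion, and
takes the trapezoidal area — which equals the tie-corrected Mann–Whitney
$U/(n_1 n_2)$ (asserted to $10^{-9}$ in the tests). auROCs are computed
for cue vs baseline, reward vs control cue, and responded vs
non-responded trials (the last requiring at least five trials of each
kind). `control_auroc()` anchors the scale by discriminating two
disjoint, randomly placed baseline windows; its distribution centers on
0.5 for a stationary unit. auROC 0.5 means no discrimination.

## Firing–latency correlations and shuffle nulls

`latency_correlation()` computes the Spearman rank correlation between
per-trial firing rates and port-entry latencies over responded trials
(minimum five; average ranks for ties; exact p only for n ≤ 9 without
ties, t-approximation otherwise). The primary window is [0, 0.3) s after
cue onset; the [0.09, 0.3) variant is always computed alongside because
both definitions are in circulation and neither is privileged here.

`shuffle_null()` permutes each unit's latencies independently 1000 times,
recomputing rho and p per iteration, and records the per-iteration count
of significant units and population mean rho. A unit *exceeds shuffle*
when its observed |rho| lies above the 95th percentile of its own
shuffled |rho| distribution. The engine computes rho as Pearson on ranks
in vectorized form (permuting the centered rate ranks against fixed
latency ranks, which is equivalent to shuffling the latencies) with the
t-approximation for p; it is cross-checked against `cor.test()` in the
tests.

`sliding_window_series()` maps the correlation across 30 windows of
50 ms from 0.5 s before to 1 s after the cue. Each window's population
mean rho is tested against its own permutation null (label shuffles per
unit); windows are flagged at a per-window permutation level of 0.002,
chosen so the family-wise false-flag rate across the 30 windows stays
near 5% — a per-window 0.05 rule would flag a pre-cue window in nearly
half of null sessions and make "first flagged window" meaningless. The
flag threshold never demands a p below the permutation resolution
$1/(n_{perm}+1)$.

## Kinematics

Tracking traces are linearly interpolated per coordinate over interior
gaps, with leading/trailing gaps held at the nearest observed value;
frames inside gaps longer than 1 s are excluded (trials overlapping them
are dropped). Velocity is 30 × the Euclidean displacement between
consecutive frames, unsmoothed. `movement_onset()` finds the first of at
least five consecutive frames whose velocity exceeds the upper limit of
the 95% band of the 5 s pre-cue baseline velocity (mean + 1.96 SD, a
one-sided upward exceedance — approach can only raise velocity); a
zero-variance baseline falls back to an epsilon SD floor of 0.1 cm/s and
is flagged. `kinematic_encoding()` correlates per-trial firing with
distance from the port at cue onset, mean velocity over [0, 0.5) and
[0.5, 1.0) s, and movement-onset latency.

## Population statistics

Response-class proportions are compared across tasks with Pearson
chi-squared tests **without** continuity correction (`chi2_2x2()`,
`chi2_rxc()`); rate-encoding distributions (auROCs, correlation
coefficients) with pooled-variance two-sample t tests. When a critical
contrast is non-significant, `jzs_bayes_factor()` quantifies support for
the null: a Zellner–Siow setup with a Cauchy prior of scale
$r = \sqrt{2}/2$ on the standardized effect size, computed by numerical
integration of the JZS g-integral (tolerance $10^{-8}$), with effective
sample size $n_1 n_2/(n_1+n_2)$ for two-sample designs. BF$_{01} > 1$
favors the null; the scale is exposed as a parameter.

## The synthetic-session generator

The generator is the test bed for every stage and defines the study
conditions the tests assume:

* **Behavior** (`generate_behavior()`): interleaved reward/control trials,
  ITIs i.i.d. uniform on [25, 75] s (the stated 50 s mean with bounded
  support; the schedule's true law is not public), 10 s cues, response
  probabilities defaulting to 0.9 (reward) and 0.2 (control) — a trained
  animal comfortably past criterion — and entry latencies lognormal with
  median 1.5 s and log-SD 0.6, truncated to the cue, matching typical
  trained port-entry latencies of one to a few seconds. Nonspecific ITI
  entries arrive at 1.5/min. Contingencies are exact: instrumental
  rewarded trials truncate the cue at the entry and set the reward time
  to it; Pavlovian reward trials are rewarded at onset + 8 s regardless.
* **Units** (`generate_unit_spikes()`): inhomogeneous Poisson with a
  baseline rate (default 10 Hz, VP-typical) plus a per-trial boxcar
  response. The boxcar, rather than a decaying kernel, makes onset/offset
  ground truth unambiguous for detector tests. The per-trial gain is
  $\exp(-\beta z(\text{latency}))\cdot\exp(-\gamma z(\text{distance}))$
  with $z$ the within-session rank-normal score, so couplings are
  scale-free and $\beta = \gamma = 0$ gives gain 1 exactly. $\beta > 0$
  strengthens short-latency trials, producing negative firing–latency
  correlations; the analyses only test monotone association, which this
  satisfies. Excitations are generated by superposition and inhibitions
  by exact thinning, flooring the total rate at 0 Hz.
* **Tracking** (`generate_tracking()`): a smooth confined random walk at
  a baseline speed (4 cm/s) in a 40 cm arena, with a straight-line,
  arrival-timed approach to the port on each responded trial and a 2 s
  hold at the port afterwards; a configurable fraction of frames is
  flagged missing. The movement onset either follows from the approach
  distance and speed or can be programmed at a fixed delay for recovery
  studies.

What the generator does *not* emulate: refractoriness, bursting and
oscillations; slow drifts in excitability across a session; correlated
noise across units; reward-consumption firing; pose and heading (the
trace is a single tracked point). Passing tests therefore demonstrate the
correctness and calibration of the estimators under Poisson variability
and the stated couplings, not robustness to every property of real
recordings.

## Calibration and problem sizes used by the tests

The test suite measures, among others: type-I error of the latency
correlation on 1000 uncoupled units (required inside 0.05 ± 0.02, and the
observed significant count inside the shuffle null's central 95%);
recovery of a coupled population with $\beta = 0.24$ — chosen once so the
population mean rho is ≈ −0.3 at 25 responded trials — where the
significant-unit count must exceed the 1000-iteration null's maximum in
at least 19 of 20 master seeds; recovery of a +120 ms programmed response
onset to within one 10 ms bin in at least 95 of 100 seeds (200 trials,
strong response); and recovery of a programmed 0.4 s movement onset to
within ±0.1 s on at least 90 of 100 trials whose start distance from the
port is at least 8 cm (an animal already at the port has no approach to
detect). The acceptance script (`scripts/acceptance.R`) re-runs scaled
versions of these measurements (400 null units, 30 onset seeds) alongside
the closed-form population statistics.

## Known limitations

* The deflection-point rule's 10% threshold depends on the AIC's scale;
  it is reported per unit and should not be compared across differing
  window or trial configurations.
* Uncorrected per-bin band crossings are liberal by construction; the
  sign-rank backbone plus telescopic confirmation controls the unit-level
  class, but the `band_class` column alone should not be read as a
  calibrated detector.
* The JZS integration is accurate for |t| in the ranges exercised
  (oracle-checked to $10^{-5}$ relative); extreme t with very large n may
  need a rescaled quadrature.
* Latency correlations require five responded trials; sessions from
  poorly trained animals will return `not evaluated` rather than noisy
  estimates.
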