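# vpcue

Analysis of ventral pallidum (VP) single-unit recordings during
cue-elicited reward seeking, asking whether cue-evoked firing encodes cue
value, response likelihood, or response vigor — and whether that encoding
depends on the task contingency. Two tasks produce similar behavior from
different causal structures: an **instrumental DS task** (an auditory cue
of up to 10 s during which a port entry earns sucrose and terminates the
cue) and **Pavlovian conditioning** (a 10 s CS+ followed by sucrose 8 s
after onset regardless of behavior). The package is aimed at systems
neuroscientists analyzing per-unit spike trains with trial tables and
optional overhead tracking, and at anyone needing a tested reference for
the analysis rules below.

## What it computes

Per unit and session:

* **PSTHs with AIC bin-size selection.** The PSTH at bin width Δ is
  scored by the AIC of its piecewise-constant inhomogeneous-Poisson rate
  model, `AIC(Δ) = -2 Σⱼ Nⱼ log(Nⱼ/(nΔ)) + 2N + 2k`; the bin used is the
  *deflection point*, the smallest candidate within 10% of the optimal
  AIC.
* **Response detection.** A 99% tolerance band (mean ± 2.576 SD of
  baseline bin rates, the baseline being the 10 s pre-cue) flags
  out-of-band bins; onsets are refined telescopically (first run of three
  consecutive 10 ms bins beyond the 10 ms band) and offsets require 300 ms
  back inside the band. Classification rests on a Wilcoxon signed-rank
  test of 300 ms post-cue versus baseline firing, with rank-sum tests for
  reward-vs-control-cue and responded-vs-non-responded contrasts.
* **ROC discrimination.** auROC (= tie-corrected Mann–Whitney
  U/(n₁n₂)) for cue vs baseline, reward vs control cue, and responded vs
  non-responded trials, anchored by a random-baseline-window control.
* **Vigor encoding.** Trial-by-trial Spearman correlation between
  post-cue firing (0–300 ms) and port-entry latency over responded
  trials, with a 1000-iteration shuffled-latency null per unit and
  population, and a 50 ms sliding-window correlation series from −0.5 to
  +1 s.
* **Kinematics.** Tracking interpolation, frame velocity, port distance,
  movement-onset detection (first ≥5 consecutive frames above the 95%
  band of 5 s pre-cue velocity), and firing–kinematics correlations.
* **Population statistics.** Uncorrected Pearson chi-squared contrasts of
  encoding proportions across tasks, pooled-variance t tests on auROC
  distributions, and scaled JZS Bayes factors (Cauchy prior, scale √2/2)
  for null-favoring contrasts.

A synthetic-session generator (`generate_session()`) emulates both task
structures — trial schedules with 50 s mean ITI, inhomogeneous-Poisson
units whose response gain can be coupled to entry latency and port
distance, and 30 fps tracking traces — so every stage is exercisable and
calibrated without the original recordings (which are not deposited).

## Worked example

```r
library(vpcue)

# an instrumental session: 12 units, the 6 excited ones with their
# response gain coupled to entry latency (beta = 0.5)
cfg_i <- default_sim_config("instrumental", n_excited = 6, n_inhibited = 3,
                            n_none = 3, latency_coupling = 0.5)
ses_i <- generate_session(cfg_i, seed = 42)
behavior_summary(ses_i)[c("p_respond_reward", "criterion_met")]

cfg <- default_analysis_config(); cfg$n_shuffle <- 500
m <- analyze_session(ses_i, cfg, seed = 1)
m[1:6, c("unit_id", "response_class", "onset_s",
         "auroc_reward_vs_control", "latency_rho", "latency_p")]
```

```
<vp_session> instrumental task: 60 trials (30 reward), 12 units, 118 port entries
reward-cue response probability: 0.97 (criterion met: TRUE)

  unit_id response_class onset_s auroc_reward_vs_control latency_rho latency_p
1    exc1        excited    0.06                   0.920      -0.645  1.58e-04
2    exc2        excited    0.07                   0.918      -0.613  4.08e-04
3    exc3        excited    0.14                   0.858      -0.527  3.32e-03
4    exc4        excited    0.06                   0.921      -0.704  2.01e-05
5    exc5        excited    0.11                   0.877      -0.457  1.27e-02
6    exc6        excited    0.08                   0.871      -0.728  7.75e-06
```

Every coupled unit is classified `excited` with an onset near the
programmed 50 ms, discriminates reward from control cue well above
chance (auROC ≈ 0.86–0.92), and fires more on short-latency trials
(negative rho, all significant). Comparing against an *uncoupled*
Pavlovian session of the same size:

```r
cfg_p <- default_sim_config("pavlovian", n_excited = 6, n_inhibited = 3,
                            n_none = 3, latency_coupling = 0)
cfg_p$behavior <- behavior_gen_params(task_kind = "pavlovian")
mp <- analyze_session(generate_session(cfg_p, seed = 43), cfg, seed = 1)
summarize_population(m, mp)
```

```
latency-predicting units: 6/12 vs 0/12 (chi2 = 8.000, p = 0.005)
auROC task contrast: t(22) = 0.06, p = 0.95; BF01 = 2.68
```

The two populations discriminate cue identity equally well (the Bayes
factor favors the null), yet only the instrumental population predicts
response latency — the dissociation the pipeline is designed to measure.

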