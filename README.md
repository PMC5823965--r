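# stopERP

Simulation and analysis of emotional auditory stop-signal experiments with
event-related potentials (ERPs), for cognitive-neurophysiology researchers
and methodologists who want a fully synthetic, fully reproducible testbed
for stop-signal behaviour and ERP pipelines.

## The problem and the models

In the stop-signal task a participant performs a speeded binary choice (a
left/right arrow) and must withhold the response when an auditory stop
signal — here an aversive noise (EMO) or a neutral tone (NEU) — follows the
go stimulus after a stop-signal delay (SSD). The package implements the
complete computational chain of such an experiment:

* **Task simulator** — the independent horse-race model: a response occurs
  on a stop trial iff the go finishing time `T_go` (ex-Gaussian) satisfies
  `T_go < SSD + T_stop`, with a condition-dependent normal stop latency
  `T_stop`. A single one-up/one-down staircase, shared by both conditions,
  adapts the SSD in 50-ms steps over 100–400 ms (start 150 ms) and converges
  on ~50% inhibition. Stop trials are exactly balanced over conditions,
  sounds, arrows and consecutive-condition sequences.
* **Behaviour** — the integration (rank-order) estimate of the stop-signal
  reaction time, `SSRT = Q_go(p(respond)) − mean SSD` with
  `n = ⌈p·N⌉`, globally and per condition (condition-wise mean SSD via the
  follower-delay bookkeeping appropriate to a shared staircase).
* **Synthetic EEG** — 32 channels at 256 Hz with planted Gaussian-bump
  components (go-evoked wave; stop-locked N1, P3; response-locked ERN, Pe
  on failed stops only), 1/f + white noise, and injected suprathreshold
  artifacts. Cross-subject structure links the error positivity to the
  failed-stop N1/P3 amplitudes (generating R² ≈ 0.66) and component
  latencies to stopping speed.
* **ERP analysis** — epoching with baseline correction, ±65 µV artifact
  rejection, per-SSD equal-weight subaveraging (which removes the
  differential go/stop overlap between conditions), and mean-amplitude /
  peak-latency scoring of N1 (120–190 ms), P3 (270–400 ms), ERN (0–80 ms)
  and Pe (120–270 ms) on their electrode clusters.
* **Statistics** — paired t with d_av and d_z, 2×2 repeated-measures ANOVA
  with partial η² = F·df₁/(F·df₁ + df₂), standardized multiple regression,
  Pearson correlations, dependent-correlation (Steiger) Z tests,
  Lilliefors/KS normality screening, Bonferroni correction, and
  noncentral-t power for paired designs.

See the methods vignette (`vignettes/stop-signal-erp-methods.Rmd`) for the
models, parameter choices and numerical conventions.

## Worked example

```r
library(stopERP)

sess <- simulate_session(session_config(), race_params(), seed = 4)
b <- behavioral_summary(sess)
round(unlist(b[1, c("mean_go_rt", "inhibition_rate_global",
                    "inhibition_rate_emo", "inhibition_rate_neu",
                    "ssrt_global", "ssrt_emo", "ssrt_neu")]), 1)
#>             mean_go_rt inhibition_rate_global    inhibition_rate_emo
#>                  374.4                   49.0                   56.0
#>    inhibition_rate_neu            ssrt_global               ssrt_emo
#>                   42.0                  207.1                  199.2
#>               ssrt_neu
#>                  214.6
```

One 400-trial session: the mean go RT is ~375 ms; the shared staircase held
the global inhibition rate near 50%; aversive stop signals were inhibited
more often (56% vs 42%) and faster — the estimated SSRT is ~15 ms shorter
in the emotional condition (199 vs 215 ms), recovering the 15-ms stopping
advantage built into the default race parameters (202 vs 217 ms).

Statistics utilities work directly from printed summary numbers as well:

```r
power_paired_t(32, 0.5, alpha = 0.05, tails = 1)  # 0.869
partial_eta_sq(5.20, 1, 31)                       # 0.14
cohens_d_av(203.3, 23.3, 217.3, 23.3)             # 0.60
```

The full simulate-and-analyse run over a cohort — EEG synthesis, epoching,
rejection, equal-weight SSD collapsing, component scoring, ANOVAs,
regressions and the latency–SSRT correlation comparison — is:

```r
report <- run_pipeline(pipeline_config(n_subjects = 32, master_seed = 1))
print(report)          # behavioural contrasts, ERP effects, regressions
```

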