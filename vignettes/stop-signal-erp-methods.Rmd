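---
title: "Simulating and analysing an emotional auditory stop-signal ERP experiment"
author: "stopERP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing an emotional auditory stop-signal ERP experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(stopERP)
```

## The task and the race model

The package simulates and analyses an emotional stop-signal task: a primary
binary-choice go task (a left/right arrow, responded to with the matching
key) in which a quarter of the trials additionally present an auditory stop
signal — an aversive noise (EMO condition) or a neutral tone (NEU) —
instructing the participant to withhold the response. The default session
design is 8 blocks of 50 trials with 100 stop trials, five sounds per
condition, each presented equally often with each arrow, and a semirandom
condition order in which the four ordered condition pairs of consecutive
stop trials are as close to equally frequent as integer arithmetic allows
(99 transitions cannot split into four equal counts; the short pair is
necessarily a repetition pair, which follows from counting in- and
out-degrees of the two-condition transition graph; the sequence is realised
as a feasibility-checked random Eulerian walk).

Behaviour follows the independent horse-race model: on a stop trial a go
process with ex-Gaussian latency (defaults `go_mu = 330`, `go_sigma = 40`,
`go_tau = 45` ms, giving a mean go RT near 375 ms) races a stop process that
starts at the stop-signal delay (SSD) and finishes after a normally
distributed stop latency (truncated at 1 ms). A response is emitted iff the
go process finishes strictly before SSD + stop latency; ties favour
stopping, a measure-zero convention under continuous latencies. Default
stop-latency means are 202 ms (EMO) and 217 ms (NEU): a 15-ms aversive
stopping advantage, the effect the task is designed to detect. A go process
that never finishes (omission) or finishes after the response deadline
produces no response; on a stop trial that counts as a successful stop.

The SSD is controlled by a single one-up/one-down staircase shared by both
conditions: 50-ms steps on a 100–400 ms lattice (seven reachable values),
starting at 150 ms, up after a successful inhibition and down after a failed
one. The shared staircase is what equates the SSD distributions of the two
conditions, which matters for the ERP overlap problem below. A
one-up/one-down rule converges on the delay where inhibition succeeds about
half the time; across 200 simulated default sessions the mean inhibition
rate is within a point and a half of 50% (slightly below it, as boundary and
lattice effects predict).

## SSRT estimation

The stop-signal reaction time (SSRT) is estimated with the integration
(rank-order) method: the no-stop-signal go RTs are pooled, rank ordered, the
n-th value is selected with n = ⌈p(respond) · N⌉ (clamped to [1, N]; the
ceiling is the conventional choice and `rank_rule` exposes floor/round
alternatives), and the mean SSD is subtracted. Condition-wise SSRTs use the
condition-wise probability of responding and a condition-wise mean SSD
defined through the staircase bookkeeping: the mean of the delays realised
on the stop trial immediately following each stop trial of that condition.
The initial delay belongs only to the global mean, and the final stop trial
contributes no follower. By default the go-RT distribution includes
wrong-key responses on no-stop trials (`include_go_errors = FALSE` restricts
it to hits), since the estimator's description refers to responses to go
stimuli rather than correct responses; the flag documents the ambiguity.

Two properties of the estimator are worth noting, both visible in the test
suite. First, with a constant stop latency and a fixed SSD the estimator is
consistent: the p(respond)-quantile of the go distribution converges on
SSD + stop latency, so the estimated SSRT converges on the true latency
(asserted within 5 ms at N = 10,000). Second, under the full staircase the
estimate carries a small bias: mixing over the visited SSDs makes the
response probability a concave average, which pulls the global estimate a
few milliseconds below the true mean stop latency (about −4 ms at the
default settings, asserted within ±10 ms at cohort scale), and the
follower-SSD bookkeeping slightly inflates the estimated condition
difference (about +2–3 ms on an injected 15-ms effect, asserted within
±5 ms over replicated 32-subject cohorts). An incidental observation from
the simulator: if the stop latency is made deterministic, the coarse shared
staircase can lock into near-periodic orbits that almost equalise the two
conditions' response rates; trial-to-trial stop-latency variability (the
default `stop_sd = 30` ms) is what makes the condition effect recoverable.

## The synthetic EEG

`synthesize_session_eeg()` lays the session's trials end to end on a 256-Hz,
32-channel montage (extended 10–20 sites) and plants Gaussian-bump component
templates, each defined by a peak latency, a full width at half maximum and
a fixed scalp weight map that is maximal over the component's analysis
cluster (a two-level map; no forward head model is attempted):

* a go-locked evoked wave on every trial (peak 250 ms, FWHM 250 ms) — the
  source of go/stop overlap;
* stop-locked N1 (peak 155 ms, FWHM 70 ms, negative) and P3 (condition-wise
  peak latencies, defaults 337.4 ms EMO / 368.7 ms NEU, FWHM 130 ms,
  positive) on stop trials, with amplitudes per trial-type × condition cell;
* response-locked ERN (peak 40 ms, FWHM 60 ms, negative) and Pe
  (condition-wise peaks, 190.5 / 217.9 ms, FWHM 150 ms, positive) on failed
  stops only. Correct responses carry no error components and successful
  stops no response marker, by construction.

Cell amplitude means follow the characteristic pattern of emotional
stop-signal experiments (N1 and P3 larger for aversive sounds and for
successful stops, Pe larger after aversive errors, ERN comparable).
Between-subject structure separates a *level* component from a *condition
difference*: subject N1 and P3 levels are drawn with correlation 0.16, and
the subject Pe level is 0.82 · P3 − 0.22 · N1 plus a residual sized so the
generating R² is 0.663; the emotional-minus-neutral differences use betas
0.60 / −0.22, predictor correlation 0.33 and generating R² 0.321. Peak
latencies of the failed-stop P3 and the error Pe are coupled to the
subject's standardized stopping speed with correlations 0.60/0.38 (P3) and
−0.32/−0.25 (Pe), so the cross-subject latency–SSRT analyses have signal to
find. Between-subject SD defaults (5–6 µV for component levels, 2–3 µV for
condition differences, 16–30 ms for latencies) are chosen to be realistic
for clean adult EEG and are stated once here; they are deliberately not
tuned to reproduce any particular published table beyond its ordinal
pattern.

Background activity is a 1/f ("pink", 3 µV SD, spectrally shaped) plus
white (1.5 µV SD) mixture per channel. Large square-pulse artifacts
(100 µV, 50 ms) are injected with probability 0.06 per trial, placed inside
the trial's analysis segment so that the nominal artifact probability equals
the expected rejected fraction of analysed epochs. No ocular or muscle
morphology is modelled: independent-component cleaning is outside the
package's scope, so generating artifacts that would require it would only
misrepresent what threshold rejection can do.

What the generator does *not* emulate — volume conduction, correlated
channel noise, latency jitter within a subject, drifts, line noise — bounds
what passing tests show about real recordings: they validate the estimators
and the averaging algebra, not robustness to every physiological nuisance.

## Epoching, rejection, and overlap-equating averaging

Epochs are cut stop-locked (−100..700 ms, baseline −100..0 ms) and
response-locked (−150..600 ms, baseline −150..−50 ms). Time-to-sample
mapping is `round(t · fs / 1000)` relative to the lock sample, windows
inclusive at both mapped endpoints; at 256 Hz the stop-locked window is
samples −26..179, i.e. 206 samples. Whether the analysis windows are
inclusive at both edges is a convention; this one is used consistently for
scoring windows as well. Epochs with any value beyond ±65 µV (strict
inequality) are rejected automatically; rejection is idempotent and the
kept/rejected split is logged.

Because the stop signal follows the go stimulus by only 100–400 ms, go- and
stop-evoked activity overlap, and the overlap inside a stop-locked epoch is
a pure function of the SSD. Two conditions that visit the same SSD lattice
with different frequencies therefore differ in expected overlap under naive
pooled averaging even when their stop-locked components are identical. The
remedy implemented in `average_by_ssd_equal_weight()` is to average within
each SSD bin first and then average the bin means with equal weight
(`min_per_bin` defaults to 1, since no minimum bin occupancy is part of the
design; it is configurable). The test suite constructs exactly the adverse
case — identical planted stop components, mirrored SSD visit counts — and
asserts that equal-weight collapsing shrinks the spurious condition
difference by more than a factor of five relative to pooled averaging.

Components are scored on cluster-mean waveforms: N1 over
FC1/FC2/C3/C4/Cz/CP1/CP2 at 120–190 ms; P3 and Pe over Cz/CP1/CP2/P3/P4/Pz
at 270–400 and 120–270 ms; ERN over F3/F4/Fz/FC1/FC2/C3/C4/Cz at 0–80 ms.
Mean amplitude is the plain mean over the cluster × window grid; peak
latency is the polarity-appropriate extremum of the cluster-mean trace, ties
resolving to the earliest sample.

## The statistics layer

The group analyses mirror what such a study reports. Paired contrasts
return both paired-design effect sizes — d_av (|mean difference| over the
average condition SD, recomputable from printed means and SDs) and d_z
(t/√n) — because published d values for paired contrasts are computed under
either convention and are not always internally consistent; results label
the variant. The 2 × 2 repeated-measures ANOVA is a full within-subject
sums-of-squares decomposition; every effect has df (1, n−1), is testable
against its own effect-by-subject interaction, equals the squared paired t
of its contrast, and carries partial η² = F/(F + n − 1). Regressions are
ordinary least squares on z-scored variables with per-coefficient t at
n − k − 1 df. The dependent-correlation comparison (two correlations
sharing one variable) uses Fisher-transformed correlations with the
asymptotic covariance term; the default "updated" variant plugs the average
of the two compared correlations into that term, which improves small-sample
behaviour, and the classic variant (individual correlations) is available
because the exact small-sample correction in use varies across the
literature. Its type-I error at n = 32 is verified at 5% ± 1 point over
10,000 simulated null replicates. Paired-t power uses the noncentral t
distribution (two-sided power counts both rejection regions, so it equals α
exactly at zero effect). Normality screening defaults to the
Lilliefors-corrected Kolmogorov–Smirnov test, since the plain KS p value is
conservative when the normal parameters are estimated from the sample; the
classic test is available by flag. Bonferroni correction is `min(1, p·m)`.

## The pipeline

```{r, eval = FALSE}
cfg <- pipeline_config(n_subjects = 32, master_seed = 1)
report <- run_pipeline(cfg)
print(report)
```

`run_pipeline()` simulates the cohort, synthesizes and scores each
subject's EEG (four stop cells SUCC/UNSUCC × EMO/NEU by equal-weight SSD
collapsing, plus HIT and per-condition error cells response-locked), and
produces the behavioural contrasts, the component ANOVAs, both
cross-subject regressions (failed-stop N1/P3 amplitudes predicting the
error Pe; emotional-minus-neutral differences predicting the Pe
difference), the SSRT–latency correlations with their dependent-correlation
comparison, and a normality screen. A master seed derives all per-subject
seeds, making every table reproducible bit for bit; `out_dir` writes the
tables as CSV, and trial tables, event markers and scalar settings
round-trip through CSV/TSV/YAML.

Note one deliberate asymmetry: measured amplitudes are template amplitudes
scaled by the kernel's window mean plus overlap, so the pipeline reproduces
the *ordinal* amplitude pattern and the linking structure, not the numeric
microvolt values of any published table; and the measured cross-subject R²
of the amplitude regression sits below the generating 0.66 because
measurement noise attenuates it — with noise and residuals switched off it
rises above 0.95, the remainder being stop-locked activity bleeding into
the response-locked scoring window, which is a real feature of the design,
not an estimator defect.

## Problem sizes and numerical choices

The simulation-based checks use sizes chosen to keep Monte-Carlo error well
inside the asserted tolerances: 200 sessions for the staircase-convergence
check, N = 10,000 for the estimator-consistency check, ten replicated
32-subject cohorts for the condition-effect recovery, 300 replicated
cohorts for regression parameter recovery, 10,000 replicates for the
dependent-correlation null, and 2,000 for the t/ANOVA type-I screens.
Degenerate inputs have defined behaviour throughout: a zero-variance paired
difference gives t = 0 and p = 1 when the means agree; quantile ranks clamp
to [1, N]; collapsing the SSD lattice to one value disables the staircase;
flat waveforms take the earliest window sample as their peak; rejection at
exactly the threshold keeps the epoch (strict inequality); and collinear or
zero-variance regressors fail with the offending predictor named.

## Known limitations

Behavioural realism stops at the independent race: no trigger failures
beyond the optional omission probability, no go-RT slowing after stop
trials, no fatigue or block effects. The EEG is a linear template-plus-noise
model with stationary noise and fixed within-subject latencies. Real-data
ingestion is limited to the same containers the generators emit (trial-table
CSV, epoch arrays); no continuous-EEG file formats, filtering, re-referencing
or source analysis are provided.
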