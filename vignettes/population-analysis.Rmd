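---
title: "Population analysis of decision variables in cued-access drinking sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population analysis of decision variables in cued-access drinking sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twocap)
```

## Overview

`twocap` implements a population-level analysis of prefrontal recordings from
two-way conditioned access protocol (2CAP) drinking sessions, together with a
synthetic session generator that plants known ground truth so every stage of
the pipeline can be validated end to end. This vignette documents the methods:
the task model, the behavioral estimators, the spike-train preprocessing, the
subsampled PCA with stability selection, and the numerical conventions the
implementation commits to.

## Task model

A session consists of 48 CS+ and 48 CS− trials (`sim_config()` defaults). Each
CS+ trial is a 4 s auditory cue followed by 8 s of fluid access at one of two
sippers on opposite ends of the arena. The interval from the end of one CS+
trial to the next CS+ onset is drawn pseudorandomly from
{20, 28, 36, 44, 56, 68, 96, 120} s. CS− trials are interleaved so that
consecutive trials alternate type with probability 0.6 and every CS− stays at
least 3 s away from the flanking CS+ trial boundaries
(`assert_schedule_legal()` checks all of this).

Behavior follows a two-state seeking model: the per-trial approach probability
switches from `p_approach_high` (0.9) to `p_approach_low` (0.2) at a planted
CS+ trial index (`change_point_trial`, default 25). Approaches go to the cued
sipper with probability 0.9 and correct approaches end in drinking with
probability 0.95.

## Synthetic tracking and spiking

Snout tracking is simulated at 30 Hz with 2 px Gaussian jitter. Conditioned
approaches are modeled as stereotyped responses, which is what makes
initiation a detectable state transition for the estimator below:

* a session-level approach latency base drawn uniformly from 1–2 s, with
  0.1 s per-trial jitter;
* a ballistic dart to the sipper with a constant 0.5 s movement time (speed
  scales with distance);
* a session-level central staging point where the snout idles between trials
  (12 px per-visit scatter).

These are deliberate realism assumptions — conditioned responses are
temporally stereotyped and animals station at preferred locations — and they
are limits of the generator: if real animals in a dataset wander slowly toward
the sipper over several seconds, the approach-likelihood change point will
systematically lag true initiation.

Each unit's firing rate follows a log-linear model

```
lambda_i(t) = exp( log(baseline) + sum_s L_is * gain[group, s] * g_s(t) )
```

with four latent signals: `seek`, a boxcar covering the 6 s before CS onset on
pre-change-point CS+ trials only; `cue`, an alpha kernel (tau = 1.2 s)
spanning the cue presentation after CS+ onset; `approach`, a 3 s linear ramp
to true initiation with a 0.5 s decay; and `drink`, an alpha kernel
(tau = 0.5 s) after the true drink time. Spikes are an inhomogeneous Poisson
process at 10 ms rate resolution with continuous spike times. The generator
refuses configurations whose realized instantaneous rate exceeds `rate_cap`
(200 Hz) rather than silently clipping. Each unit also receives a mean
waveform from a narrow-fast (putative inhibitory) or broad-slow (putative
excitatory) template plus noise.

## Behavioral estimators

**Session change point.** `change_point_rss()` is an exhaustive single-split
residual-sum-of-squares minimizer: for every admissible split index it fits a
constant to each side and keeps the split with the lowest total RSS
(`min_seg = 2` enforces at least two observations per side). Exact ties break
toward the earliest split, using a relative tolerance of
`1e-9 * (1 + RSS_total)` so that floating-point noise cannot move a tie.
Constant sequences have no change point (`NA`). `session_change_point()`
applies this to the binary CS+ approach sequence ordered by CS+ index.

**Approach initiation.** `approach_likelihood()` computes, for each CS+ trial
and each 100 ms bin in the 12 s after cue onset, a weighted average of the
*other* trials' approach labels, with weights proportional to inverse
Euclidean distance in the z-scored (x, y, vx, vy) state space
(`eps = 1e-6` regularizes zero distances). Trials that end at the sipper have
high likelihood late in the window whether or not they approached early, so
the informative structure is *when* each trial's likelihood rises;
`detect_approach_initiation()` takes the RSS change point of each approached
trial's likelihood trace as its initiation time.

**Surrogates.** Trials without a real event (no approach, or no drink) receive
surrogate event times resampled from the session's real events
(`assign_surrogate_times()`), so event-aligned tensors keep every trial
without inventing structure; the surrogate flag column preserves the
distinction.

## Preprocessing

Spike trains are binned in half-open 100 ms bins (`bin_spikes()`) and smoothed
with a per-unit Gaussian whose SD is 25% of the unit's mean inter-spike
interval (`smooth_adaptive()`). The kernel is truncated at 4 SDs and
renormalized *per source bin*, so the total spike count of every unit is
conserved exactly even at the session edges; units with fewer than two spikes
pass through unsmoothed (and are flagged). Rates are aligned to four events —
CS+ onset (−10 to +20 s), every CS onset (−10 to +20 s), approach initiation
(−5 to +2 s), and drink (−10 to +10 s) — z-scored per unit across its aligned
samples, averaged within trial splits (pre/post change point, CS+/CS−,
approach/no-approach, drink/no-drink), and concatenated into one
1748-bin profile per unit (segments a±, b±, c±, d± of 301, 301, 301, 301, 71,
71, 201 and 201 bins).

## Subsampled PCA and stability

`subsample_design()` draws, per iteration, an equal number of units from every
group; `run_subsampled_pca()` runs `prcomp` (centered, unscaled) on each
subsample. Because PCA signs are arbitrary, `align_pc_signs()` iteratively
flips iterations whose score trace correlates negatively with the mean trace,
propagating every flip to the coefficients so scores remain exactly the
centered projection of the data. A component is **stable** when the variance
of its mean trace exceeds the variance of the deviations around it
(`pc_stability()`, ratio > 1); a zero deviation denominator maps to the
sentinel ratio `1e12` rather than `Inf` so downstream arithmetic stays finite.

Group trajectories are the mean centered projection of each group's units
across iterations (`project_group()`), restricted to stable components (PC1 if
none are stable). Representation strength in an epoch is the mean per-bin
Euclidean distance between two trajectory segments (`pc_separation()`,
`epoch_mean_separation()`); the five epochs are seeking (pre-CS on CS+,
−2.5 to −0.6 s), cs_onset (post-onset vs pre-onset within CS+), cs_discrim
(CS+ vs CS− at 2.0–3.9 s), approach (−3.0 to −1.1 s before initiation), and
drink (0–1.9 s after drink start).

Two controls guard against spurious separation: `shuffle_null()` permutes the
trial-split labels and recomputes the epoch separation (100 shuffles by
default), and `leave_one_out()` repeats the analysis holding out each animal.

## Waveform classification

Mean waveforms are rescaled so the trough is −1 and the post-trough
depolarization peak is +1 (`normalize_waveform()`). The time from the trough
to the 50% (value 0) and 95% (value 0.9) depolarization levels — with linear
interpolation between samples — gives `t50` and `t95`
(`depolarization_delays()`). A seeded 2-means partition of the standardized
features labels the faster-rising cluster putative inhibitory; points more
than 4 SDs from their centroid on either feature, or units whose features
could not be computed, are outliers (`classify_units()`).

## Problem sizes and runtime

The defaults (500 subsample iterations of 200 units per group, 250 units per
simulated group) reflect full-scale analyses. The examples in this vignette
and the package tests use reduced sizes chosen for quick iteration — 32 + 32
trials, 50–60 units, 20–100 iterations of 40–120 units — which this package
adopts as its own working scale for validation; all estimators are
scale-independent.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_neurons = 60L, baseline_rate = 3, loading_spread = 0.1,
                  signal_gains = list(high = c(seek = 1.5, cue = 1,
                                               approach = 1, drink = 1)),
                  seed = 11L)
s <- simulate_session(cfg, group = "high", seed = 11L)

pcfg <- pipeline_config(n_iterations = 50L, n_per_group = 40L, n_pcs = 8L)
sd1 <- process_session(s, pcfg)
pa <- population_analysis(list(sd1), pcfg)

pa$stability                      # variance-ratio stability per PC
pa$separations$high$seeking$mean  # seeking-epoch separation
```

## Limitations

* The generator's stereotypy assumptions (fixed travel time, narrow latency
  jitter, central staging point) are favorable to the approach-initiation
  estimator; less stereotyped behavior degrades it gracefully but measurably.
* The session change point is estimated from a binary Bernoulli sequence;
  with 48 CS+ trials and approach probabilities 0.9/0.2, trial noise places a
  hard ceiling (~80%) on recovering the planted trial within ±1, so
  single-session change points should be treated as ±2–3 trial estimates.
* Stability selection assumes the latent signals have distinct variances;
  exactly degenerate signals rotate freely between subsamples and their
  individual ranks are not identifiable (the shared subspace still is).
* The E/I classification is a feature-space heuristic standing in for manual
  curation; it is validated against planted templates, not against ground
  truth optotagging.
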