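---
title: "Synthetic cohorts and response-feature analysis for intracellular recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic cohorts and response-feature analysis for intracellular recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephyscohort)
```

## What this package models

Leech segmental ganglia contain identified neurons whose responses to
somatic current injection differ sharply by cell type: T3 touch
mechanoreceptors fire a variable number of spikes with short, precise
latency and decelerating inter-spike intervals (ISIs); P1 pressure
mechanoreceptors fire variably but rhythmically, with a preferred ISI near
42 ms; Retzius (Rz) neurons fire a consistent 2-5 spikes with a long,
variable latency and never fire rebound spikes after release from
hyperpolarization. Over repeated stimulation the mechanoreceptors become
more excitable (most of the change within the first ten trials) while Rz
cells become less excitable, and all types slowly hyperpolarize under
repeated stimulation.

The package provides, as testable code, the full analysis chain for such
experiments:

1. **Protocols** (`build_stim_protocol()`, `build_control_protocol()`): a
   30 s stimulation trial of fifteen 500 ms current pulses (-2 to +1.5 nA
   in 0.25 nA steps, each amplitude once, pseudo-randomized per seed),
   repeated for 20 trials; and a sparse control trial of two test pulses
   followed by 5 min of silence, repeated three times. In both protocols
   the final measurement falls 10 min after the first.
2. **A synthetic-cohort generator** (`cohort_config()`,
   `simulate_cohort()`): phenomenological voltage traces with full ground
   truth.
3. **Feature extraction** (`detect_spikes()`, `extract_trial_features()`):
   the eight per-trial response features.
4. **Nonparametric statistics** (`spearman_test()`, `rank_sum_test()`,
   `signed_rank_test()`, `coefficient_of_variation()`,
   `bonferroni_alpha()`).
5. **Orchestration** (`run_full_analysis()`, `write_report()`, and the
   `inst/cli/cohort-pipeline.R` script).

## The trace model

The generator is deliberately phenomenological, not conductance-based. One
trial's membrane potential is assembled as

* the trial's resting level: a per-cell resting membrane potential (RMP)
  drawn from a normal distribution truncated to -65..-35 mV, plus a
  protocol-dependent drift that approaches its per-cell asymptote with a
  time constant of 5 trials (stimulation) or 0.7 trials (control);
* a first-order RC response (membrane time constant 18-25 ms by type) to
  the injected current, Ohmic for hyperpolarizing current and saturating
  (about 7 mV, tanh) for depolarizing current -- near spike threshold real
  membranes engage outward conductances and the voltage-current curve
  flattens, and this also keeps the depolarized plateau well below the
  spike-detection floor so that detection is driven by spikes, not noise;
* a sag component during hyperpolarizing pulses: a slow (120 ms) relaxation
  toward a less negative plateau. Its amplitude is solved numerically per
  pulse so that the *measured* sag ratio (trough minus last-50 ms plateau,
  over the passive response) equals the cell's latent sag ratio on the
  noiseless trace; a closed-form amplitude would under-deliver because the
  RC rise is still short of plateau at the trough time;
* stereotyped spikes: a ~2 ms triangular-rise/exponential-decay template
  whose peak sits at -10 mV (sd 1 mV) in the measured trace, inserted at
  generated spike times;
* a rebound depolarization and rebound spikes after the -2 nA pulse
  (mechanoreceptors only; Rz cells never rebound);
* a linear electrode-offset ramp from 0 to a per-cell end offset drawn from
  Normal(-2.66, 3.37) mV, reached at the end of the recording;
* white membrane noise (default sd 1.5 mV);
* for T3 cells under the control protocol, occasional small synaptic bumps
  in quiet periods (qualitative only; they are not a quantified feature).

Spike counts follow a saturating threshold-linear fI law: for a pulse of
amplitude $I$,

$$ n = \mathrm{round}\!\left(\min\left(n_{\max},\;
   e(\mathrm{trial})\, g\, (I - \theta)_+ \,\varepsilon\right)\right), $$

with threshold $\theta = 0.3$ nA, per-type gain $g$, saturation
$n_{\max}$, a multiplicative per-pulse noise $\varepsilon$
(log-normal, sd ~0.16), and a trial-dependent excitability

$$ e(\mathrm{trial}) = e_0 \left(1 + \beta \left(1 -
   e^{-(\mathrm{trial}-1)/\tau}\right)\right), \qquad \tau = 3
   \text{ trials}, $$

so that more than 95% of the excitability change is completed within ten
trials. The trend $\beta$ is positive for T3/P1 and negative for Rz, with
per-cell spread so that a realistic minority of mechanoreceptor cells fail
to increase their count.

First-spike latency is log-normal per cell (scaled by pulse strength and a
slow upward trial trend); ISI sequences are archetype-specific:
decelerating (each interval 8% longer than the last, with the starting
interval shrinking for high-count trains), rhythmic (i.i.d. jitter around
the cell's preferred interval), or broad log-normal. Spikes scheduled past
the pulse end are truncated, never wrapped -- for rhythmic P1 trains this
truncation is what caps feasible counts near twelve spikes per 500 ms
pulse, mirroring the observed ceiling.

### Cell-level heterogeneity and the copula

RMP, excitability, rebound propensity and latency scale are drawn from a
Gaussian copula (`sample_cell_latents()`) whose pairwise Spearman
correlations are configured per archetype (latent Pearson correlations are
obtained via $r = 2\sin(\pi\rho_s/6)$, so the rank correlations survive the
marginal transforms exactly). Excitability and rebound propensity have
mean-one gamma marginals -- the gamma shape reproduces both the large
spike-count dispersion and the small zero-count mass that a log-normal
cannot deliver simultaneously. Input resistance, sag ratio, trend, drift
and electrode offset are drawn independently.

The configured correlation targets are deliberately somewhat stronger than
the values the pipeline is meant to recover (e.g. RMP-excitability -0.49
for a recovered RMP-count correlation near -0.40): integer rounding of
spike counts attenuates rank correlations by roughly 15%, and the
calibration absorbs that attenuation. All defaults live in
`cell_type_params()` and were frozen once against the target summary
statistics by simulation; they are not adjusted per run.

### Seeding

A cohort seed splits into per-cell and per-(cell, trial) child seeds by a
fixed arithmetic rule, so enlarging a cohort never perturbs earlier cells
and simulating a trial subset reproduces exactly the trials a full run
would have produced. Protocol construction uses a private RNG state and
never disturbs the simulation stream.

## Feature definitions and numerical choices

* **Spike detection**: local maxima with absolute height >= -20 mV,
  topographic prominence >= 10 mV, and >= 5 ms separation (the detector's
  source convention of 50 samples at 10 kHz, enforced in milliseconds so
  lower sampling rates behave identically; at 50 *ms* the decelerating T3
  trains with 23 ms intervals would be merged, so the samples reading is
  the only consistent one). On a separation conflict the higher peak wins.
* **RMP**: median over the second immediately before the +1 nA pulse
  (18-19 s stimulation, 4.5-5.5 s control); the median is robust to spike
  or synaptic transients inside the window.
* **Spike count / rebound count / latency / ISIs**: peak times inside the
  half-open +1 nA window (19.0-19.5 s) or the 500 ms rebound window after
  the -2 nA pulse; latency is pulse onset to first *peak*; undefined
  features (no spikes, control-protocol rebound/sag) are an explicit `NA`,
  never 0 -- the zero-versus-absent distinction drives downstream sample
  sizes.
* **Passive response, sag, input resistance**: medians of the last 50 ms of
  the -2 nA pulse and of the 500 ms before onset; the trough is the pulse
  minimum after excluding the first 5 ms (onset transient) on a 5 ms
  moving-average-smoothed copy, so the estimate reflects the sag trajectory
  rather than the single most extreme noise sample; input resistance is
  |passive| / 2 nA.
* **Delta features**: final minus initial trial (20 vs 1, or 3 vs 1), with
  the final RMP first corrected by `correct_final_rmp()` assuming a linear
  electrode drift over the recording.
* **Inclusion filter**: cells with zero spikes in both the first and final
  trial are excluded (and logged) before any statistic.

## Statistics

All tests are two-sided and use midranks for ties. `spearman_test()`
enumerates the exact permutation null up to n = 9 and uses the
t-approximation above; `rank_sum_test()` and `signed_rank_test()` report
the normal-approximation Z with tie and continuity corrections (the
convention of the package's comparison tables) and use the exact
`pwilcox`/`psignrank` null for untied samples up to n = 25. Zero
differences are dropped before signed ranking; an all-zero sample returns
p = 1 with a warning. The coefficient of variation uses the n-1 sample
standard deviation (the cohorts are small). `bonferroni_alpha(0.05, 5)`
gives the corrected level 0.01 used for the protocol-comparison block,
while the correlation block stays at 0.05; reported p-values render as
"<0.01" / two decimals at the 0.05 level and "<0.001" / three decimals at
the corrected level.

The exact-versus-approximate branch points (9 and 25) are desk-scale
choices: below them exhaustive enumeration is cheap and removes any
approximation question; above them the approximations are accurate to well
under the rounding used in the rendered tables. Both branches are exposed
(`exact_limit`) so tests can pin either.

## What the generator does and does not establish

Passing recovery tests on synthetic cohorts shows that the *pipeline* --
detection, windowing, deltas, correlations, tests -- measures what the
generator put in, at realistic noise, sample sizes and effect sizes. It
does not validate the generator against real recordings: real spike
waveforms vary within and across cells, noise is colored, electrode drift
is not exactly linear, and confounders are inert here by construction
(temperature, leech, ganglion and experimenter fields are populated but
causally disconnected unless the corresponding knob is set). The
`rmp_shift` knob exposes batch effects (e.g. seasonal differences between
protocol groups) but defaults to zero, treating both protocol arms as
drawn from identical populations.

## Problem sizes and runtime

The recovery checks simulate cohorts at the study's sample sizes (67/29/21
stimulation cells and a 23-cell subset) at a 2 kHz sampling rate; all
features are sample-rate robust by construction and test, and 2 kHz keeps
a full cohort under a minute on one core. The native rate of the emulated
recordings (10 kHz) is the package default for data export. Statistical
recovery at these n is inherently noisy: a cohort median latency carries a
~5% sampling error, dispersion and correlation estimates ~0.08-0.1, and
the 23-cell increase fraction ~7 percentage points; the recovery
tolerances in the test suite are set accordingly, and individual seeds can
and do land outside them occasionally without indicating a defect.

## Known limitations

* The pulse-order permutation is fixed per protocol seed and shared across
  trials; whether real session orders varied per trial is unknown, and no
  feature here depends on the order of the unanchored pulses.
* Control-protocol trials are rendered only over their first 10 s (all
  measurement windows end by 6 s); the 5 min quiet tails exist on the
  trial clock (drift, offset) but are not synthesized sample-by-sample,
  so spontaneous activity in the quiet period is not modeled.
* Rebound spike timing is stereotyped (first spike ~15 ms after release);
  only counts are analyzed.
* The generator treats archetype parameters as stationary within a cohort;
  slow seasonal or batch drifts are available only through `rmp_shift`.
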