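---
title: "Models and methods: LFP seizure detection and behavioral phenotyping"
author: "seizescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: LFP seizure detection and behavioral phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seizescreen)
```

# Scope

`seizescreen` implements the computational pipeline of a large-scale larval
zebrafish epilepsy screen: local field potential (LFP) recordings from the
optic tectum are scanned for electrographic events, events are classified
into interictal-like (type I) and ictal-like (type II) classes, each 15 min
epoch receives an LFP score in {0, 1, 2}, and genotype groups are called
epileptic when their mean score reaches 1.0. Around this core sit a
movement-bout analysis of swim trajectories with a convulsive
("seizure-like") event flag, survival statistics (Kaplan-Meier, log-rank),
a gene-orthology homology score, and a synthetic-data module that generates
all three data types with ground truth so that every stage is testable
without access to recordings.

# The event detector

## Model

A recording is a uniformly sampled voltage trace $v_i$ (mV) at rate $f_s$
(10 kHz in the screening design, low-pass filtered at 1 kHz during
acquisition). Detection proceeds in three steps:

1. **Binarize.** Sample $i$ is active iff $|v_i - \mathrm{median}(v)| \ge T$.
   The threshold $T$ is either absolute (legal range 0.05-1.0 mV; the screen
   tuned within 0.15-0.25 mV depending on noise) or relative,
   $T = k\,\hat\sigma$ with $k = 3$ by default. The relative form is the
   default because it adapts to the recording's noise level; at the
   generator's baseline $\sigma = 0.05$ mV the absolute range 0.15-0.25 mV
   corresponds to $3\sigma$-$5\sigma$, so the two forms are consistent.
   All comparisons are inclusive ($\ge$).
2. **Raster score.** The trace is cut into 10 ms bins; the score of bin $i$
   is the fraction of active samples in the window $[t_i, t_i + W)$
   starting at that bin, truncated at the trace end. Scores lie in [0, 1].
3. **Segment.** Maximal runs of bins with score $\ge \theta$ (raster
   threshold, legal range 0.05-0.8, default 0.3, screen range 0.2-0.4)
   become events; runs separated by at most `min_event_gap_bins`
   sub-threshold bins are merged. Event boundaries are reported at bin
   resolution.

## Why the analysis window defaults to 0.02 s

The window length $W$ is configurable; its default is two bins (0.02 s),
deliberately close to the bin width. The reason is arithmetic: with a long
window a brief event cannot reach the raster threshold at all — a fully
active event of duration $d$ inside a window of length $W$ scores at most
$d/W$, so with $W = 0.5$ s even a 99 ms interictal event peaks at
$0.198$, below the whole working threshold range $\theta \in [0.2, 0.4]$.
Detecting the 10-99 ms interictal class at these thresholds, and measuring
its duration to within a few percent, requires $W$ of the same order as the
bin. A short window also keeps the boundary smearing small: a detected run
overestimates a fully active event by about $W(1 - 2\theta)$ plus one bin
of quantization, i.e. a few milliseconds at the defaults.

The long-gap merge default (`min_event_gap_bins = 25`, 250 ms) is the
counterpart for the ictal class: a multi-spike burst with a within-burst
spike rate of 5-20 Hz has spike gaps up to 200 ms, and with a fine window
those gaps fall below the raster threshold. Merging across up to 250 ms of
sub-threshold bins keeps a burst one event while leaving well-separated
events (the generator enforces at least 0.35 s separation) distinct.

## Noise estimate

"Baseline noise" is operationalized robustly: the trace is cut into 1 s
segments, the half with the lowest segment SD is kept (this excludes
event-contaminated stretches), and the noise SD is
$1.4826 \times \mathrm{MAD}$ of the kept samples. On pure Gaussian noise
the estimate is unbiased to within a few percent and a single multi-second
large-amplitude burst does not move it. The flip side of keeping the
quietest half is that post-ictal suppression, if it occupies a large
fraction of a short trace, deflates the estimate; on 15 min epochs at
realistic ictal rates the suppressed fraction is about a percent and the
effect is negligible.

## Spike counting

`n_spikes` counts distinct super-threshold excursions within an event,
debounced in two steps: excursions separated by less than 4 ms merge (the
two opposite-polarity lobes of one biphasic deflection straddle a brief
zero crossing, and threshold flicker on a plateau would otherwise be
over-counted), then merged spikes narrower than 2 ms are discarded —
the acquisition low-pass (1 kHz) correlates samples, so isolated noise
crossings last a few samples and never form a 2 ms excursion. With this
definition a single sharp wave counts one spike and a 5-20 Hz burst counts
its constituent spikes.

## Threshold tuning

Mirroring the screen's own validation, `tuneThresholds()` grid-searches the
absolute voltage threshold over 0.15-0.25 mV and the raster threshold over
0.2-0.4, detects events on a short reference epoch (typically 10 s), and
returns the grid point minimizing the relative discrepancy in total event
duration against reference (manual or ground-truth) marks. A tuning is
accepted only below 3%; ties break toward the smaller voltage then the
smaller raster threshold. A count-based comparison is available as an
option (`compare = "count"`), since which quantity the original <3% rule
compared is ambiguous.

# Event typing and the LFP score

Type II (ictal-like): peak deviation $\ge 5\hat\sigma$, duration in
[45, 5090] ms, and at least 2 spikes (the class is defined by multi-spike
morphology; without the spike gate, any sufficiently large single sharp
wave lasting over 45 ms would be promoted to type II, which contradicts
both the taxonomy and the observed rarity of ictal activity in wild-type
recordings). Type I (interictal-like): peak $\ge 3\hat\sigma$ and duration
in [10, 99] ms. The ranges overlap on [45, 99] ms; type II is tested first
so the more severe class takes precedence. Everything else is type 0.

A recording scores 2 with any type II event; 1 with at least 3 type I
events and no type II (a lone sharp wave should not make an epoch
"type I" — the count is configurable); else 0. The per-genotype epilepsy
call is `mean score >= 1.0`: the source text states both "1.0 or above"
and "> 1.0", and the inclusive reading was chosen. Post-ictal suppression
is declared when the RMS of the 5 s after an event is at most half the
baseline noise SD; when less than a full window of trace remains the
result is flagged partial.

# Behavior

Swim speed is the frame-to-frame Euclidean displacement times the frame
rate (25 fps). Movement events are maximal stretches with speed
$\ge 0.9$ mm/s; stretches separated by less than 40 ms are combined
*before* discarding events shorter than 160 ms (merge-then-filter: the
stated purpose of merging is to let brief sub-bouts form one valid
movement, which the opposite order would defeat). The data-driven
high/low speed cutoff is mean + 1.5 SD of the per-movement maximum-speed
distribution of a control cohort (the phrase "1.5x standard deviation"
omits its center; mean-anchoring is the conventional reading and is
applied per cohort). Seizure-like events are movements with maximum speed
$\ge 28$ mm/s lasting $\ge 1$ s; high-speed events (HSE) use the same
28 mm/s cutoff without the duration gate. All comparisons are inclusive;
the source mixes ">" and ">=" at 28 mm/s and inclusivity was chosen for
consistency with the detector.

# Synthetic data

The generators are the package's test bed: they reproduce the statistical
structure the analyses assume, with known ground truth, a single integer
seed for all randomness, and bit-identical output for identical
(parameters, seed).

**LFP.** Baseline noise is Gaussian, shaped by a 4th-order Butterworth
low-pass at 1 kHz and rescaled to $\sigma = 0.05$ mV. Interictal-like
events are biphasic transients with short (1.5 ms) cosine ramps flanking
two opposite-polarity plateaus (the second at 85% amplitude, polarity
random); amplitudes are drawn from 3-8$\sigma$ and durations from
10-99 ms. The plateaued shape is a deliberate idealization: the source
gives no waveform equation, and a plateau makes the nominal support and
the super-threshold extent coincide, so ground-truth durations are
well-defined and the <3% tuning comparison is meaningful. Ictal-like
events are bursts of such transients at 5-20 Hz spread from burst start to
burst end (amplitudes 5-15$\sigma$, durations 45-5090 ms), each followed
by a suppression stretch (2-10 s) in which the noise SD is halved. Events
are placed uniformly at random subject to a 0.35 s minimum separation
(stick-breaking placement), and a load above half the epoch is rejected
as infeasible.

**Wild-type defaults are calibrated to the study's printed summaries.**
The WT ictal rate is $-\ln(1 - 0.147) \approx 0.159$ per 15 min, so the
fraction of WT epochs containing an ictal event matches the reported
14.7%; the WT interictal rate is 0.16/min (2.4 per epoch), so with
$P(\mathrm{Pois}(2.4) \ge 3) \approx 0.43$ the expected WT LFP score is
close to the reported 0.66 (detection-boundary losses near the 99 ms
type-I ceiling push the realized value a few percent lower). An
"epileptic line" preset raises the ictal rate to 3 per epoch.

**Tracks.** A piecewise speed profile — sub-0.9 mm/s rest jitter,
raised-cosine bouts (rate 6/min, durations 0.2-0.8 s, log-normal peak
speeds), and trapezoidal sustained high speed with erratic heading for
seizure-like events (peaks 30-40 mm/s, durations 1.2-3 s) — is integrated
along random headings with reflection at a circular arena wall of radius
3.5 mm (96-well scale). The bout peak-speed distribution
(meanlog = log 10.1, sdlog = 0.35) is tuned so that the detected
per-movement mean maximum speed is 10.5 mm/s with bout durations under
1 s, matching the printed control summary. An optional convulsant dose
raises the seizure rate linearly (0.4 events/15 min per mM) and, at doses
of 10 mM and above, kills a larva with probability
$1 - e^{-0.02\,\mathrm{exposure~(min)}}$, freezing it — which reproduces
the reported drop in detected events at high dose and long exposure.

**Survival.** Death times are Weibull with the requested median and shape
12 (a steep larval die-off concentrated within about a day of the
median), rounded up to half days because larvae are checked twice daily,
and censored at 13 dpf by default.

**What the generators do not emulate.** Real recordings contain electrode
drift, movement artifacts, line noise, non-Gaussian background and
waveform families far richer than a two-parameter transient; real tracks
contain wall-following, burst-and-glide microstructure and tracker noise.
Passing the recovery and calibration suites therefore demonstrates the
correctness and internal consistency of the algorithms under the stated
statistical assumptions — not detector performance on real data, which
the original screen established by manual comparison.

# Numerical conventions

* All threshold comparisons are inclusive; boundary fixtures assert this.
* Intervals are half-open $[t_0, t_1)$ seconds from recording start;
  event durations are multiples of the 10 ms bin.
* Track gaps of at most 5 frames are linearly interpolated; longer gaps
  are logged and excluded from speed computation; more than 50% missing
  frames is a quality error.
* The tuning grid uses steps of 0.0125 mV and 0.025; ties resolve to the
  smaller voltage, then the smaller raster threshold.
* Median survival is the earliest time with survival at or below 0.5.
* p values are two-sided. The pooled two-sample t test reproduces the
  printed degrees of freedom (969 for 781 + 190 larvae; 353 for 56 + 299);
  Welch and Mann-Whitney variants are provided because the source's
  "non-parametric t test" wording is contradictory. Group-vs-control
  comparisons are emitted unadjusted for multiplicity.
* The homology score is $(\mathrm{identity~\%} + 100 k / 12) / 2$ over
  $k$ of 12 ortholog-prediction tools, with a strict $> 65$ inclusion
  gate.

# Problem sizes used in the test-suite

The suites run the full 15 min / 10 kHz epoch where a printed quantity
depends on it (the 200-recording type-II calibration, the 50-larva
behavioral calibration, the two-line end-to-end screen at 20 larvae per
line) and shorter epochs (30 s-5 min) elsewhere, chosen so each property
is measured at the scale that determines it.

# Known limitations

* Event boundaries are quantized to 10 ms bins; durations inherit a bias
  of order $W(1-2\theta)$ plus one bin, so events genuinely at the 99 ms
  type-I ceiling can be measured past it and fall to type 0.
* The two-rater human scoring of the original screen is emulated by a
  deterministic decision rule (optionally averaged over a second
  configuration pass); agreement with human scores on real data is out
  of scope.
* The log-rank and Kaplan-Meier layers delegate to the survival package;
  they are validated against hand-computed tables, not re-derived.
* Single-electrode recordings only; no artifact rejection beyond the
  robust noise estimate.
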